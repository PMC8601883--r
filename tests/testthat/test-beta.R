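test_that("Jaccard distances follow set arithmetic and ignore abundances", {
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], sprintf("r%d", 1:4)))
  m[c("a", "b", "c"), 1] <- 5L
  m[c("b", "c", "d"), 2] <- 1L
  m[c("a", "b", "c"), 3] <- 99L
  m[c("d"), 4] <- 2L
  D <- as.matrix(jaccard_distance(m))
  expect_equal(D["r1", "r2"], 0.5)        # {abc} vs {bcd}: 1 - 2/4
  expect_equal(D["r1", "r3"], 0)          # same set, different counts
  expect_equal(D["r1", "r4"], 1)          # disjoint
  # invariance to column rescaling
  m2 <- m; m2[, 2] <- m2[, 2] * 17L
  expect_equal(as.matrix(jaccard_distance(m2)), D)
  # empty columns have distance 0 by convention
  e <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_equal(max(as.matrix(jaccard_distance(e))), 0)

  skip_if_not_installed("vegan")
  set.seed(6)
  x <- matrix(rbinom(60, 1, 0.5) * rpois(60, 9), 10, 6)
  ours <- as.matrix(jaccard_distance(x))
  ref <- as.matrix(vegan::vegdist(t(x), method = "jaccard", binary = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("Bray-Curtis matches its formula and warns on unequal depths", {
  m <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_equal(as.matrix(bray_curtis_distance(m))["r1", "r2"], 1)
  expect_equal(as.matrix(bray_curtis_distance(cbind(m[, 1], m[, 1])))[1, 2], 0)
  expect_warning(bray_curtis_distance(matrix(c(1, 1, 5, 5), 2)), "rarefied")

  skip_if_not_installed("vegan")
  set.seed(7)
  x <- matrix(rpois(50, 6), 10, 5)
  x <- sweep(x, 2, colSums(x), "/") * 1000  # equalize depths
  expect_equal(unname(as.matrix(suppressWarnings(bray_curtis_distance(x)))),
               unname(as.matrix(vegan::vegdist(t(x), method = "bray"))),
               tolerance = 1e-9)
})

test_that("LCBD decomposes total variance, sums to one, and flags the odd replicate", {
  # two replicates with disjoint single taxa: symmetric halves
  m <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("a", "b"), c("r1", "r2")))
  lr <- lcbd(m, n_perm = 49, seed = 1)
  expect_equal(lr$table$lcbd, c(0.5, 0.5))

  tt <- random_table(S = 12, R = 6, lambda = 5, seed = 9)
  for (tr in c("hellinger", "none")) {
    lr2 <- lcbd(tt, transform = tr, n_perm = 19, seed = 2)
    expect_equal(sum(lr2$table$lcbd), 1, tolerance = 1e-9)
    expect_true(all(lr2$table$lcbd >= 0))
    expect_equal(lr2$table$lcbd,
                 lcbd_bruteforce(tt$counts, hellinger = tr == "hellinger"),
                 tolerance = 1e-9)
  }

  # degenerate: identical replicates
  same <- matrix(4L, 3, 5, dimnames = list(letters[1:3], sprintf("r%d", 1:5)))
  ld <- lcbd(same, n_perm = 19, seed = 3)
  expect_true(ld$degenerate)
  expect_equal(ld$table$lcbd, rep(0.2, 5))

  # 5 near-identical replicates + 1 disjoint: the outsider carries the
  # largest LCBD and is called an outlier in nearly every seeded run
  hits <- 0
  for (s in 1:10) {
    base <- matrix(rep(c(30L, 20L, 10L, 5L), 6), 4,
                   dimnames = list(letters[1:4], sprintf("r%d", 1:6)))
    odd <- matrix(0L, 4, 6)
    odd[, 6] <- c(-30L, -20L, -10L, 60L)  # replicate 6: only taxon d
    x <- base + odd
    lr3 <- lcbd(x, n_perm = 999, seed = 100 + s)
    if (which.max(lr3$table$lcbd) == 6 && lr3$table$p_adjusted[6] <= 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("PCoA reproduces hand eigendecompositions and round-trips Euclidean input", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  p <- pcoa(D)
  expect_equal(sum(p$eigenvalues > 1e-9), 1)
  ax <- p$points[, 1]
  expect_equal(unname(sort(ax)), c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(ncol(p$imaginary_points), 0)

  z <- pcoa(matrix(0, 3, 3))
  expect_equal(z$eigenvalues, rep(0, 3))
  expect_equal(ncol(z$points), 0)

  set.seed(12)
  X <- matrix(rnorm(14), 7, 2)
  pe <- pcoa(dist(X))
  rec <- dist(pe$points)
  expect_equal(as.numeric(rec), as.numeric(dist(X)), tolerance = 1e-9)

  # non-Euclidean Jaccard: B is reconstructed from all (real and imaginary)
  # axes, and eigenvalues match an independent implementation
  tt <- random_table(S = 10, R = 6, lambda = 1, seed = 4)
  D2 <- jaccard_distance(tt)
  pj <- pcoa(D2)
  M <- as.matrix(D2)
  A <- -0.5 * M^2
  J <- diag(6) - matrix(1 / 6, 6, 6)
  B <- J %*% A %*% J
  recon <- tcrossprod(pj$points) - tcrossprod(pj$imaginary_points)
  expect_lt(max(abs(B - recon)), 1e-9)
  skip_if_not_installed("ape")
  ref <- ape::pcoa(D2)
  k <- ncol(pj$points)
  expect_equal(pj$eigenvalues[1:k], ref$values$Eigenvalues[1:k],
               tolerance = 1e-9)
})

test_that("chi-square outlier-count tests follow the Pearson/Yates rules", {
  r0 <- outlier_count_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- outlier_count_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r1$statistic, 16.2)          # Yates-corrected Pearson
  expect_lt(r1$p_value, 0.001)
  r2 <- outlier_count_test(matrix(c(3, 7, 3, 7, 3, 7), 2))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$df, 2)
  expect_error(outlier_count_test(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)),
               "marginal")
  expect_error(outlier_count_test(matrix(1, 1, 2)), "2x2")
})
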