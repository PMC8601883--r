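test_that("alpha indices match closed forms and the vegan oracle", {
  a <- alpha_indices(c(10, 10, 10, 10))
  expect_equal(a$observed, 4)
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 0.75)
  b <- alpha_indices(c(7, 0, 0))
  expect_equal(unlist(b), c(observed = 1, shannon = 0, simpson = 0))
  d <- alpha_indices(c(4, 3, 2, 1))
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(d$shannon, -sum(p * log(p)))
  expect_equal(d$simpson, 0.70)
  expect_equal(unlist(alpha_indices(c(0, 0))),
               c(observed = 0, shannon = 0, simpson = 0))
  expect_error(alpha_indices(c(-1, 3)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:5) {
    x <- rpois(12, 8)
    expect_equal(alpha_indices(x)$shannon,
                 unname(vegan::diversity(x, "shannon")), tolerance = 1e-12)
    expect_equal(alpha_indices(x)$simpson,
                 unname(vegan::diversity(x, "simpson")), tolerance = 1e-12)
  }
})

test_that("alpha indices are invariant to permutation and integer rescaling", {
  set.seed(4)
  x <- rpois(15, 6)
  a <- alpha_indices(x)
  perm <- alpha_indices(sample(x))
  scl <- alpha_indices(7L * x)
  expect_equal(perm$shannon, a$shannon)
  expect_equal(scl$shannon, a$shannon)
  expect_equal(scl$simpson, a$simpson)
  expect_equal(scl$observed, a$observed)
})

test_that("interpolated richness obeys its boundary identities", {
  x <- c(8, 5, 3, 2, 1)
  expect_equal(interpolated_richness(x, sum(x)), 5)
  expect_equal(interpolated_richness(c(99, 1), 10), 1.1)
  expect_equal(interpolated_richness(x, 1), 1)
  expect_error(interpolated_richness(x, sum(x) + 1), "extrapolated")
  # matches repeated rarefaction on a small column (quick version of the
  # simulation-oracle equivalence; the full check lives in the acceptance suite)
  est <- interpolated_richness(x, 7)
  draws <- vapply(1:800, function(i) sum(rarefy(x, 7, seed = i) > 0), 0L)
  expect_lt(abs(mean(draws) - est), 3 * sd(draws) / sqrt(800))
})

test_that("extrapolation reproduces the Chao1 worked example and its limits", {
  r <- extrapolated_richness(c(4, 3, 2, 1, 1), 0)
  expect_equal(r$f1, 2)
  expect_equal(r$f2, 1)
  expect_equal(r$f0_hat, (10 / 11) * 4 / 2)
  expect_equal(r$s_hat, 5 + 20 / 11)        # 6.8181...
  expect_equal(r$estimate, 5)               # continuity at m* = 0

  # no singletons: curve collapses to S_obs
  flat <- extrapolated_richness(c(5, 4, 3), 1000)
  expect_equal(flat$estimate, 3)
  expect_equal(flat$s_hat, 3)

  # monotone approach to the asymptote
  x <- c(4, 3, 2, 1, 1)
  n <- sum(x)
  ms <- c(0, n, 2 * n, 5 * n, 10 * n)
  est <- vapply(ms, function(m) extrapolated_richness(x, m)$estimate, 0)
  expect_true(all(diff(est) > 0))
  expect_true(all(est <= extrapolated_richness(x, 0)$s_hat))
  expect_lt(extrapolated_richness(x, 0)$s_hat -
              extrapolated_richness(x, 10 * n)$estimate, 0.05)
})

test_that("richness curves are anchored at S_obs with sane bootstrap SEs", {
  x <- c(20L, 12L, 6L, 3L, 1L, 1L, 1L)
  cur <- richness_curve(x, knots = 20, nboot = 30, seed = 9)
  n <- sum(x)
  expect_true(n %in% cur$m)
  expect_equal(cur$richness[cur$m == n], 7)
  expect_true(all(diff(cur$richness) >= -1e-9))
  expect_true(all(cur$method[cur$m <= n] == "interpolated"))
  expect_gt(cur$se[cur$m == n], 0)   # unseen-taxon uncertainty when f1 > 0
  expect_identical(richness_curve(x, knots = 20, nboot = 30, seed = 9), cur)
  single <- richness_curve(c(50L), knots = 10, nboot = 20, seed = 2)
  expect_true(all(single$se == 0))
  expect_true(all(single$richness == 1))
})

test_that("IQR outlier calls follow the type-7 fence rule", {
  r <- iqr_outliers(c(10, 11, 12, 13, 50))
  expect_equal(r$q1, 11)
  expect_equal(r$q3, 13)
  expect_equal(c(r$lower, r$upper), c(8, 16))
  expect_equal(which(r$outlier), 5)
  expect_false(any(iqr_outliers(rep(3, 6))$outlier))
  r2 <- iqr_outliers(c(1, 2, 3, 4))
  expect_equal(c(r2$q1, r2$q3), c(1.75, 3.25))
  expect_equal(c(r2$lower, r2$upper), c(-0.5, 5.5))
  expect_false(any(r2$outlier))
  expect_error(iqr_outliers(c(1, 2, 3)), "at least 4")
})

test_that("depth contrasts report Welch t, p, and fold changes per extract", {
  rec <- data.frame(
    replicate_id = rep(sprintf("r%d", 1:4), 2),
    extract_id = "E1",
    depth = rep(c(1000, 10000), each = 4),
    observed = c(10, 11, 10, 11, 20, 22, 20, 22),
    shannon = rep(1, 8), simpson = rep(0.5, 8))
  out <- depth_contrast_tests(rec, 1000, 10000)
  obs <- out[out$index == "observed", ]
  expect_equal(obs$fold_change, 2, tolerance = 1e-9)
  sh <- out[out$index == "shannon", ]
  expect_equal(sh$t, 0)
  expect_equal(sh$p_value, 1)
  expect_equal(attr(out, "mean_fold_observed"), 2, tolerance = 1e-9)
  # identical groups: t = 0, p = 1, fold = 1
  rec2 <- rec
  rec2$observed <- rep(c(10, 11, 10, 11), 2)
  out2 <- depth_contrast_tests(rec2, 1000, 10000)
  obs2 <- out2[out2$index == "observed", ]
  expect_equal(obs2$t, 0)
  expect_equal(obs2$p_value, 1)
  expect_equal(obs2$fold_change, 1)
})
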