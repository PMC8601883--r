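test_that("sample_community honours the closed forms and its contracts", {
  expect_equal(sample_community(3, "geometric", g = 0.5), c(4, 2, 1) / 7)
  expect_equal(sample_community(1, "geometric", g = 0.3), 1)
  expect_equal(sample_community(1, "lognormal", sigma = 1, seed = 1), 1)
  expect_error(sample_community(3, "geometric", g = 0), "g must be")
  expect_error(sample_community(3, "geometric", g = 1.2), "g must be")
  expect_error(sample_community(3, "lognormal", sigma = 0), "sigma")

  p1 <- sample_community(200, "lognormal", sigma = 2, seed = 7)
  p2 <- sample_community(200, "lognormal", sigma = 2, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  expect_equal(sum(p1), 1)
  expect_true(!is.unsorted(rev(p1)))   # sorted descending
})

test_that("simulate_replicates: depths are exact, seeds reproduce, theta limit is binomial", {
  law <- list(meanlog = log(10000), sdlog = 0, min = 10000, max = 10000)
  sim <- simulate_replicates(c(0.5, 0.5), 20, theta = 1e12, depth_law = law,
                             seed = 5)
  expect_equal(unname(colSums(sim$table$counts)), rep(10000, 20))
  # theta -> infinity: counts ~ Binomial(10000, 0.5); 4 sigma = 200
  expect_true(all(abs(sim$table$counts[1, ] - 5000) < 4 * 50))

  sim2 <- simulate_replicates(c(0.5, 0.5), 20, theta = 1e12, depth_law = law,
                              seed = 5)
  expect_identical(sim2$table$counts, sim$table$counts)

  empty <- simulate_replicates(c(0.7, 0.3), 0, theta = 10, depth_law = law)
  expect_equal(ncol(empty$table$counts), 0)
  expect_error(simulate_replicates(c(1, 0) / 1, 2, theta = 0, depth_law = law),
               "theta")
})

test_that("Dirichlet-multinomial mean matches p and noise grows as theta shrinks", {
  p <- c(0.55, 0.25, 0.12, 0.05, 0.03)
  law <- list(meanlog = log(5000), sdlog = 0, min = 5000, max = 5000)
  R <- 240
  sim <- simulate_replicates(p, R, theta = 5, depth_law = law, seed = 21)
  freq <- sweep(sim$table$counts, 2, colSums(sim$table$counts), "/")
  for (i in seq_along(p)) {
    mc_sigma <- sd(freq[i, ]) / sqrt(R)
    expect_lt(abs(mean(freq[i, ]) - p[i]), 3 * mc_sigma + 1e-9)
  }
  vars <- vapply(c(5, 50, 500), function(th) {
    s <- simulate_replicates(p, 100, theta = th, depth_law = law, seed = 33)
    f <- sweep(s$table$counts, 2, colSums(s$table$counts), "/")
    var(f[1, ])
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("controls and spikes are injected as configured", {
  base <- random_table(S = 30, R = 12, lambda = 40, seed = 2)
  cfg0 <- synthetic_config(n_contaminants = 1,
                           contaminant_prevalence_in_controls = 1,
                           contaminant_prevalence_in_samples = 0,
                           n_extraction_controls = 4, n_pcr_controls = 0,
                           hop_rate = 0, seed = 9)
  sp <- spike_contaminants_and_controls(base, cfg0)
  ctrl_cols <- sp$metadata$replicate_id[sp$metadata$sample_type ==
                                          "extraction_control"]
  contam <- sp$table$counts["contaminant_01", ]
  expect_equal(sum(contam > 0), 4)
  expect_true(all(names(contam[contam > 0]) %in% ctrl_cols))
  # hop_rate 0: spike confined to its own column
  pos_col <- sp$metadata$replicate_id[sp$metadata$sample_type ==
                                        "positive_control"]
  spike <- sp$table$counts[cfg0$spike_taxon, ]
  expect_equal(sum(spike[setdiff(names(spike), pos_col)]), 0)
  expect_equal(unname(spike[pos_col]), cfg0$spike_depth)

  # hop_rate 0.01 at spike depth 100,000: hops within 4 sigma of 1,000
  cfg1 <- synthetic_config(hop_rate = 0.01, seed = 13)
  sp1 <- spike_contaminants_and_controls(base, cfg1)
  sigma <- sqrt(100000 * 0.01 * 0.99)
  expect_lt(abs(sp1$hopped_reads - 1000), 4 * sigma)
  hop <- index_hop_check(sp1$table, sp1$metadata, cfg1$spike_taxon)
  expect_lt(abs(hop$rate - 0.01), 4 * sigma / 100000)
})

test_that("a full experiment regenerates identically from config + seed", {
  cfg <- synthetic_config(n_extracts = 2, replicates_per_extract = 3,
                          richness_per_extract = 25, markers = c("PITS", "FITS"),
                          seed = 17)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  for (mk in names(a)) {
    expect_identical(a[[mk]]$table$counts, b[[mk]]$table$counts)
    expect_identical(a[[mk]]$metadata, b[[mk]]$metadata)
  }
  # abundance ground truth sums to one per extract
  for (ab in a$PITS$truth$extract_abundances)
    expect_lt(abs(sum(ab) - 1), 1e-12)
  # contaminants are disjoint from community taxa
  expect_length(intersect(a$PITS$truth$contaminant_ids,
                          sprintf("taxon_%04d", seq_len(cfg$pool_richness))), 0)
  # depth law respected
  d <- replicate_depths(a$PITS$table)
  samp <- a$PITS$metadata$replicate_id[a$PITS$metadata$sample_type == "sample"]
  expect_true(all(d[samp] >= cfg$depth_law$min & d[samp] <= cfg$depth_law$max))
})
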