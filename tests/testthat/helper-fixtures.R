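# Small in-code fixtures shared across test files.

# A fixed 4-taxon x 3-replicate table with lineage.
tiny_table <- function() {
  m <- matrix(c(5L, 0L, 2L, 3L,
                0L, 3L, 2L, 1L,
                4L, 4L, 0L, 0L), nrow = 4,
              dimnames = list(c("sp1", "sp2", "sp3", "sp4"),
                              c("r1", "r2", "r3")))
  taxon_table(m, lineage = c(
    sp1 = "family:Poaceae;genus:Stipa;species:Stipa pulchra",
    sp2 = "family:Poaceae;genus:Avena",
    sp3 = "family:Asteraceae;genus:Baccharis",
    sp4 = NA))
}

# Random integer taxon table under a fixed seed.
random_table <- function(S = 8, R = 5, lambda = 10, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  m <- matrix(rpois(S * R, lambda), S, R,
              dimnames = list(sprintf("t%02d", seq_len(S)),
                              sprintf("r%02d", seq_len(R))))
  taxon_table(m)
}

# Metadata for n sample columns plus controls, matching a table's columns.
meta_for <- function(tab, n_sample, n_ctrl = 0, n_pos = 0,
                     extract = "E1", marker = "M1") {
  ids <- colnames(tab$counts)
  stopifnot(length(ids) == n_sample + n_ctrl + n_pos)
  replicate_metadata(
    replicate_id = ids,
    extract_id = c(rep(extract, n_sample), rep("control", n_ctrl + n_pos)),
    marker = marker,
    sample_type = c(rep("sample", n_sample),
                    rep("extraction_control", n_ctrl),
                    rep("positive_control", n_pos)))
}

# Independent brute-force LCBD (direct variance decomposition), used as the
# oracle for the packaged implementation.
lcbd_bruteforce <- function(counts, hellinger = FALSE) {
  Y <- t(counts)
  if (hellinger) {
    tot <- rowSums(Y); tot[tot == 0] <- 1
    Y <- sqrt(Y / tot)
  }
  n <- nrow(Y)
  ss_i <- numeric(n)
  for (j in seq_len(ncol(Y))) {
    mu <- mean(Y[, j])
    for (i in seq_len(n)) ss_i[i] <- ss_i[i] + (Y[i, j] - mu)^2
  }
  ss_i / sum(ss_i)
}

# Closed-form expected rarefied richness (hypergeometric miss probability).
expected_rarefied_richness <- function(x, d) {
  x <- x[x > 0]
  N <- sum(x)
  sum(1 - exp(lchoose(N - x, d) - lchoose(N, d)))
}
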