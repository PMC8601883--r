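#' Alpha-diversity indices of one replicate
#'
#' Observed richness, Shannon entropy (natural log), and the Gini--Simpson
#' index `1 - sum(p^2)`, from within-replicate read proportions.  An empty
#' column yields zeros for all three.
#'
#' @param column non-negative count vector.
#' @return A list: `observed`, `shannon`, `simpson`.
#' @examples
#' alpha_indices(c(10, 10, 10, 10))  # S = 4, H = log(4), Simpson = 0.75
#' @export
alpha_indices <- function(column) {
  if (any(column < 0)) stop("counts must be non-negative")
  n <- sum(column)
  if (n == 0) return(list(observed = 0L, shannon = 0, simpson = 0))
  p <- column[column > 0] / n
  list(observed = length(p),
       shannon = -sum(p * log(p)),
       simpson = 1 - sum(p^2))
}

#' Interpolated (rarefied) expected richness
#'
#' The closed-form expected number of taxa in a without-replacement
#' subsample of `m` reads from a column of `n` reads:
#' `S(m) = S_obs - sum_i choose(n - x_i, m) / choose(n, m)`, evaluated in
#' log space.  `S(n)` equals the observed richness exactly.
#'
#' @param column count vector.
#' @param m subsample size, `1 <= m <= sum(column)`.
#' @return Expected richness at `m` reads.
#' @examples
#' interpolated_richness(c(99, 1), 10)  # 1 + 10/100
#' @export
interpolated_richness <- function(column, m) {
  x <- column[column > 0]
  n <- sum(x)
  stopifnot(m >= 1)
  if (m > n) stop("m exceeds the column total; use extrapolated_richness()")
  miss <- exp(lchoose(n - x, m) - lchoose(n, m))
  length(x) - sum(miss)
}

#' Extrapolated richness and Chao1-type asymptote
#'
#' Sample-size-based extrapolation for Hill number q = 0: with `f1`
#' singletons and `f2` doubletons in a column of `n` reads, the number of
#' undetected taxa is estimated as
#' `f0 = ((n-1)/n) f1^2 / (2 f2)` (or `((n-1)/n) f1 (f1-1) / (2 (f2+1))`
#' when `f2 = 0`), giving the asymptote `S_hat = S_obs + f0` and
#' `S(n + m*) = S_obs + f0 (1 - (1 - f1 / (n f0 + f1))^{m*})`.
#' With no singletons the curve is flat at `S_obs`.
#'
#' @param column count vector.
#' @param m_star additional reads beyond the observed total (>= 0).
#' @return A list: `estimate` (richness at `n + m_star`), `s_hat`
#'   (asymptote), `f0_hat`, `f1`, `f2`.
#' @examples
#' extrapolated_richness(c(4, 3, 2, 1, 1), 0)$s_hat  # 6.8181...
#' @export
extrapolated_richness <- function(column, m_star) {
  stopifnot(m_star >= 0)
  x <- column[column > 0]
  n <- sum(x)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0 || n <= 1)
    return(list(estimate = as.numeric(s_obs), s_hat = as.numeric(s_obs),
                f0_hat = 0, f1 = f1, f2 = f2))
  f0 <- if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
        else ((n - 1) / n) * f1 * (f1 - 1) / (2 * (f2 + 1))
  est <- if (f0 <= 0) as.numeric(s_obs) else
    s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m_star)
  list(estimate = est, s_hat = s_obs + f0, f0_hat = f0, f1 = f1, f2 = f2)
}

# Richness estimate at an arbitrary m: interpolation below the reference
# depth, extrapolation beyond it.
richness_at <- function(column, m) {
  n <- sum(column)
  if (m <= n) interpolated_richness(column, m)
  else extrapolated_richness(column, m - n)$estimate
}

#' Interpolated/extrapolated richness curve with bootstrap uncertainty
#'
#' The sample-size-based richness curve of one replicate from 1 read to
#' `extend` times its depth (default twice), on `knots` evenly spaced
#' sample sizes including the reference depth `n`.  Uncertainty comes from
#' a Chao-adjusted bootstrap: observed proportions are shrunk by the
#' estimated sample coverage, the estimated `f0` undetected taxa share the
#' coverage deficit equally, and each of `nboot` bootstrap communities
#' redraws `n` reads multinomially.  The confidence band is the normal
#' approximation `estimate +/- z SE`.
#'
#' @param column count vector with at least one read.
#' @param knots number of sample-size knots (default 40).
#' @param nboot bootstrap replicates for the SE (default 50; `0` skips).
#' @param conf confidence level (default 0.95).
#' @param extend curve endpoint as a multiple of the reference depth.
#' @param seed optional integer seed.
#' @return A `data.frame`: `m`, `method` (`"interpolated"`/
#'   `"extrapolated"`), `richness`, `se`, `lcl`, `ucl`; the Chao1-type
#'   asymptote is attached as attribute `s_hat`.
#' @export
richness_curve <- function(column, knots = 40L, nboot = 50L, conf = 0.95,
                           extend = 2, seed = NULL) {
  x <- as.integer(column[column > 0])
  n <- sum(x)
  if (n < 1) stop("column has no reads")
  m_grid <- unique(sort(c(n, round(seq(1, extend * n, length.out = knots)))))
  est <- vapply(m_grid, function(m) richness_at(x, m), 0)
  se <- rep(NA_real_, length(m_grid))
  if (nboot >= 2) {
    boot <- with_seed(seed, {
      p_boot <- bootstrap_abundances(x)
      vapply(seq_len(nboot), function(b) {
        xb <- as.integer(rmultinom(1, n, p_boot))
        vapply(m_grid, function(m) richness_at(xb[xb > 0], m), 0)
      }, numeric(length(m_grid)))
    })
    se <- apply(matrix(boot, nrow = length(m_grid)), 1, sd)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(m = m_grid,
                    method = ifelse(m_grid <= n, "interpolated", "extrapolated"),
                    richness = est, se = se,
                    lcl = est - z * se, ucl = est + z * se,
                    stringsAsFactors = FALSE)
  attr(out, "s_hat") <- extrapolated_richness(x, 0)$s_hat
  out
}

# Chao-adjusted bootstrap community: observed proportions shrunk by the
# estimated sample coverage; ceiling(f0_hat) unseen taxa split the deficit.
bootstrap_abundances <- function(x) {
  n <- sum(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  f0 <- extrapolated_richness(x, 0)$f0_hat
  if (f1 == 0 || f0 <= 0) return(x / n)
  coverage <- 1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  n0 <- max(1L, as.integer(ceiling(f0)))
  c(x / n * coverage, rep((1 - coverage) / n0, n0))
}

#' Tukey-fence outlier flags (1.5 x IQR rule)
#'
#' Quartiles use linear-interpolation (type 7) quantiles; values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return A list: `outlier` (logical flags), `lower`, `upper`, `q1`, `q3`.
#' @examples
#' iqr_outliers(c(10, 11, 12, 13, 50))$outlier
#' @export
iqr_outliers <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 values for the IQR outlier rule")
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  list(outlier = values < lower | values > upper,
       lower = lower, upper = upper, q1 = q[1], q3 = q[2])
}

#' Depth-contrast tests of alpha diversity
#'
#' Per-extract two-sided Welch t-tests comparing each alpha index between
#' two rarefaction depths, plus the fold change of mean observed richness
#' (`d2` over `d1`).  Replicates that dropped out at either depth are
#' excluded; extracts with fewer than 2 retained replicates in either
#' group are skipped with a warning.
#'
#' @param records `data.frame` with columns `replicate_id`, `extract_id`,
#'   `depth`, and the index columns.
#' @param d1,d2 the two depths to contrast (`d2 > d1` conventionally).
#' @param indices index column names to test.
#' @return A `data.frame` (one row per extract x index): `extract_id`,
#'   `index`, `t`, `p_value`, `mean_d1`, `mean_d2`, `fold_change`;
#'   the across-extract mean fold change of observed richness is attached
#'   as attribute `mean_fold_observed`.
#' @export
depth_contrast_tests <- function(records, d1, d2,
                                 indices = c("observed", "shannon", "simpson")) {
  stopifnot(all(c("replicate_id", "extract_id", "depth") %in% names(records)),
            all(indices %in% names(records)))
  out <- list()
  for (ex in unique(records$extract_id)) {
    r1 <- records[records$extract_id == ex & records$depth == d1, ]
    r2 <- records[records$extract_id == ex & records$depth == d2, ]
    shared <- intersect(r1$replicate_id, r2$replicate_id)
    r1 <- r1[match(shared, r1$replicate_id), ]
    r2 <- r2[match(shared, r2$replicate_id), ]
    if (length(shared) < 2) {
      warning("extract ", ex, ": fewer than 2 replicates at both depths; skipped")
      next
    }
    for (idx in indices) {
      a <- r1[[idx]]; b <- r2[[idx]]
      tt <- if (var(a) == 0 && var(b) == 0) {
        list(statistic = if (mean(a) == mean(b)) 0 else NA_real_,
             p.value = if (mean(a) == mean(b)) 1 else NA_real_)
      } else t.test(b, a, var.equal = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        extract_id = ex, index = idx,
        t = unname(tt$statistic), p_value = unname(tt$p.value),
        mean_d1 = mean(a), mean_d2 = mean(b),
        fold_change = if (mean(a) > 0) mean(b) / mean(a) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  obs <- res[res$index == "observed", "fold_change"]
  attr(res, "mean_fold_observed") <- mean(obs, na.rm = TRUE)
  res
}
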