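#' Bootstrapped PCR-replicate accumulation curve
#'
#' Cumulative unique-taxon counts as replicates are added one at a time,
#' averaged over `B` uniform shuffles of the replicate order (permutations
#' without replacement, not resampling).  The saturation point is the
#' smallest replicate count `k` whose next-step increment of the
#' bootstrap-mean curve is below one taxon; if no such `k` exists within
#' the retained replicates the sentinel `"> K"` is reported, `K` being the
#' number of replicates retained after rarefaction.
#'
#' @param x a [taxon_table()] or count matrix whose columns are the
#'   retained, already filtered replicates of one extract.
#' @param B number of bootstrap shuffles (default 100).
#' @param seed optional integer seed.
#' @return A list of class `accumulation_curve`: `curve` (data.frame `k`,
#'   `mean_richness`, `sd_richness`), `increments` (mean step sizes
#'   `Delta(k) = mean(k+1) - mean(k)`), `saturation_k` (integer or `NA`),
#'   `saturation_label` (the integer as character, or `">K"`), `K`.
#' @export
accumulation_curve <- function(x, B = 100L, seed = NULL) {
  counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
  K <- ncol(counts)
  if (K < 1) stop("need at least one retained replicate")
  pres <- counts > 0
  rich <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ord <- sample.int(K)
      seen <- rep(FALSE, nrow(pres))
      out <- integer(K)
      for (k in seq_len(K)) {
        seen <- seen | pres[, ord[k]]
        out[k] <- sum(seen)
      }
      out
    }, integer(K))
  })
  rich <- matrix(rich, nrow = K)
  mean_k <- rowMeans(rich)
  sd_k <- apply(rich, 1, sd)
  inc <- if (K > 1) diff(mean_k) else numeric(0)
  sat <- if (any(inc < 1)) which(inc < 1)[1] else NA_integer_
  structure(list(
    curve = data.frame(k = seq_len(K), mean_richness = mean_k,
                       sd_richness = sd_k),
    increments = inc,
    saturation_k = sat,
    saturation_label = if (is.na(sat)) sprintf(">%d", K) else as.character(sat),
    K = K), class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("replicate accumulation over %d replicates; saturation at %s\n",
              x$K, x$saturation_label))
  print(head(x$curve, 5))
  invisible(x)
}

#' Per-taxon occupancy records
#'
#' For each taxon detected in at least one column: the number of replicate
#' columns in which it is present (its occupancy) and the mean read count
#' across the replicates where it is present.
#'
#' @param x a [taxon_table()] or count matrix of the retained, filtered
#'   replicates of one cell of the depth/threshold grid.
#' @return A `data.frame`: `taxon_id`, `occupancy`, `mean_reads_present`.
#' @export
occupancy_records <- function(x) {
  counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon_%d", seq_len(nrow(counts)))
  pres <- counts > 0
  occ <- rowSums(pres)
  keep <- occ > 0
  data.frame(taxon_id = rownames(counts)[keep],
             occupancy = unname(occ[keep]),
             mean_reads_present = unname(rowSums(counts)[keep] / occ[keep]),
             stringsAsFactors = FALSE)
}

#' Occupancy spectrum
#'
#' Histogram of taxa by the number of replicates in which they occur
#' (1 .. `K`), plus the fraction of detected taxa seen in exactly one
#' replicate -- the "replicate singletons" that dominate uneven eDNA
#' communities.
#'
#' @param x a [taxon_table()], count matrix, or the output of
#'   [occupancy_records()].
#' @param K number of retained replicates (inferred from a table input).
#' @return A list: `spectrum` (named integer vector over occupancy
#'   1 .. `K`), `n_taxa`, `singleton_fraction`.
#' @export
occupancy_spectrum <- function(x, K = NULL) {
  if (is.data.frame(x)) {
    rec <- x
    if (is.null(K)) K <- max(rec$occupancy)
  } else {
    counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
    if (is.null(K)) K <- ncol(counts)
    rec <- occupancy_records(x)
  }
  spec <- tabulate(rec$occupancy, nbins = K)
  names(spec) <- seq_len(K)
  list(spectrum = spec, n_taxa = nrow(rec),
       singleton_fraction = if (nrow(rec) > 0) spec[[1]] / nrow(rec) else NA_real_)
}

#' Occupancy--abundance regression
#'
#' Ordinary least squares of occupancy on log10 mean within-replicate read
#' count where present.  A positive, significant slope reproduces the
#' familiar pattern that abundant taxa are seen in (nearly) every PCR
#' replicate while rare taxa appear stochastically in few.  (For a simple
#' regression the slope t statistic, its p-value, and R^2 are identical
#' whichever variable is treated as the response; the log base rescales
#' the slope only.)
#'
#' @param records output of [occupancy_records()] (>= 3 taxa).
#' @return A list: `slope`, `intercept`, `t_statistic`, `p_value`,
#'   `adj_r_squared`, `n`.
#' @export
occupancy_abundance_fit <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("occupancy", "mean_reads_present") %in% names(records)))
  if (nrow(records) < 3) stop("need at least 3 taxa for the regression")
  lx <- log10(records$mean_reads_present)
  if (var(lx) == 0) stop("zero variance in log-abundance predictor")
  fit <- lm(records$occupancy ~ lx)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       t_statistic = unname(sm$coefficients[2, "t value"]),
       p_value = unname(sm$coefficients[2, "Pr(>|t|)"]),
       adj_r_squared = sm$adj.r.squared,
       n = nrow(records))
}
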