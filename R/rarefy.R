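#' Rarefy one replicate column to a fixed depth
#'
#' Subsamples exactly `depth` reads from the column's read pool uniformly
#' without replacement (a multivariate hypergeometric draw), preserving
#' taxon order.  This is true subsampling of the sequenced pool, so the
#' expected rarefied richness has the closed form
#' `E[S_d] = sum_i (1 - choose(N - x_i, d) / choose(N, d))`.
#'
#' @param column non-negative integer count vector (one replicate).
#' @param depth number of reads to draw; must satisfy
#'   `1 <= depth <= sum(column)`.
#' @param seed optional integer seed.
#' @return Integer vector of the same length and names, summing to `depth`.
#' @examples
#' rarefy(c(a = 99L, b = 1L), 10, seed = 7)
#' @export
rarefy <- function(column, depth, seed = NULL) {
  x <- as.integer(column)
  out <- with_seed(seed, .rarefy_one(x, as.integer(depth)))
  names(out) <- names(column)
  out
}

#' Apply a per-replicate minimum read threshold
#'
#' Counts below `t` are set to zero; counts of at least `t` are kept
#' unchanged (the threshold is inclusive: a taxon with exactly `t` reads
#' survives).  With `t` of 2 this removes exactly the within-replicate
#' singletons.
#'
#' @param column count vector.
#' @param t minimum read threshold (>= 0; 0 and 1 are the identity).
#' @return Thresholded count vector.
#' @examples
#' apply_min_read_threshold(c(1, 4, 5, 10), 5)
#' @export
apply_min_read_threshold <- function(column, t) {
  stopifnot(t >= 0)
  ifelse(column < t, 0L, column)
}

#' Mean rarefied richness over a depth-by-threshold grid
#'
#' The central filtering grid: for every replicate, rarefaction depth, and
#' minimum read threshold, the mean observed richness over `R` independent
#' rarefaction draws (rarefy first, then threshold).  Replicates whose
#' library depth falls below a rarefaction depth are flagged as dropped
#' out at that depth rather than raising an error, and the number of
#' retained replicates per depth is reported.  Every cell's randomness is
#' seeded as `derive_seed(seed, replicate, depth, threshold, repeat)`, so
#' any cell can be recomputed in isolation.
#'
#' @param x a [taxon_table()].
#' @param depths ascending vector of rarefaction depths.
#' @param thresholds vector of minimum read thresholds.
#' @param R number of rarefaction draws per cell (default 25).
#' @param seed integer master seed.
#' @return A list with `grid` (data.frame: `replicate_id`, `depth`,
#'   `threshold`, `mean_richness`, `dropped`) and `retained` (data.frame:
#'   `depth`, `n_retained` -- the "RAR" ledger).
#' @export
rarefaction_grid <- function(x, depths, thresholds, R = 25L, seed = 1L) {
  stopifnot(inherits(x, "taxon_table"), R >= 1)
  depths <- as.integer(depths)
  if (is.unsorted(depths, strictly = FALSE)) stop("depths must be ascending")
  totals <- replicate_depths(x)
  reps <- colnames(x$counts)
  rows <- vector("list", length(reps) * length(depths) * length(thresholds))
  k <- 0L
  for (r in reps) {
    col <- x$counts[, r]
    for (d in depths) {
      dropped <- totals[[r]] < d
      for (t in thresholds) {
        k <- k + 1L
        mr <- NA_real_
        if (!dropped) {
          acc <- 0
          for (b in seq_len(R)) {
            acc <- acc + with_seed(derive_seed(seed, r, d, t, b),
                                   .mean_rarefied_richness(col, d, as.integer(t), 1L))
          }
          mr <- acc / R
        }
        rows[[k]] <- data.frame(replicate_id = r, depth = d, threshold = t,
                                mean_richness = mr, dropped = dropped,
                                stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  retained <- data.frame(depth = depths,
                         n_retained = vapply(depths, function(d)
                           sum(totals >= d), 0L))
  list(grid = grid, retained = retained)
}
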