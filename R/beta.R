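#' Binary Jaccard dissimilarity between replicates
#'
#' Columns are reduced to presence/absence; the dissimilarity between two
#' replicates is `1 - |A intersect B| / |A union B|`.  Two empty columns
#' are assigned distance 0 by convention.  Because only presence matters,
#' the result is invariant to rescaling any column's counts.
#'
#' @param x a [taxon_table()] or count matrix (>= 2 columns).
#' @return A `dist` object labeled by replicate id.
#' @export
jaccard_distance <- function(x) {
  counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("need at least 2 replicates")
  pres <- counts > 0
  inter <- crossprod(pres)           # |A n B|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  D <- ifelse(uni > 0, 1 - inter / uni, 0)
  diag(D) <- 0
  stats::as.dist(D)
}

#' Bray--Curtis dissimilarity between replicates
#'
#' `D_ij = sum |x - y| / sum (x + y)`.  Intended for rarefied tables: a
#' warning is emitted when column sums differ, since unequal depths
#' conflate depth with composition.
#'
#' @param x a [taxon_table()] or count matrix (>= 2 columns).
#' @return A `dist` object labeled by replicate id.
#' @export
bray_curtis_distance <- function(x) {
  counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("need at least 2 replicates")
  tot <- colSums(counts)
  if (length(unique(tot[tot > 0])) > 1)
    warning("column sums differ; Bray-Curtis is meant for rarefied columns")
  n <- ncol(counts)
  D <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- tot[i] + tot[j]
    D[i, j] <- D[j, i] <- if (denom > 0)
      sum(abs(counts[, i] - counts[, j])) / denom else 0
  }
  stats::as.dist(D)
}

#' Local contributions to beta diversity (LCBD)
#'
#' Total beta diversity is measured as the total variance of the
#' (optionally Hellinger-transformed) replicate-by-taxon matrix: columns
#' are centered per taxon, squared deviations are summed, and each
#' replicate's LCBD is its share of that total sum of squares (so LCBDs
#' are non-negative and sum to one).  Significance of each LCBD is
#' assessed by permuting values independently within each taxon across
#' replicates; p-values are Holm-adjusted and a replicate is called an
#' outlier when its adjusted p is at most `alpha`.
#'
#' @param x a [taxon_table()] or count matrix (>= 2 columns).
#' @param transform `"hellinger"` (square root of within-replicate
#'   proportions; default) or `"none"`.
#' @param n_perm number of permutations (default 999).
#' @param alpha outlier call level on the adjusted p (default 0.05).
#' @param seed optional integer seed.
#' @return A list: `table` (data.frame `replicate_id`, `lcbd`, `p_value`,
#'   `p_adjusted`, `outlier`), `ss_total`, `bd_total`
#'   (`ss_total / (n - 1)`), `transform`, `degenerate` (`TRUE` when all
#'   replicates are identical, in which case LCBD is uniform `1/n`).
#' @export
lcbd <- function(x, transform = c("hellinger", "none"), n_perm = 999L,
                 alpha = 0.05, seed = NULL) {
  transform <- match.arg(transform)
  counts <- if (inherits(x, "taxon_table")) x$counts else as.matrix(x)
  n <- ncol(counts)
  if (n < 2) stop("need at least 2 replicates")
  Y <- t(counts)                              # replicates x taxa
  if (transform == "hellinger") {
    tot <- rowSums(Y)
    tot[tot == 0] <- 1
    Y <- sqrt(Y / tot)
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  S2 <- Yc^2
  ss_i <- rowSums(S2)
  ss_total <- sum(ss_i)
  ids <- colnames(counts)
  if (ss_total < 1e-12) {
    tab <- data.frame(replicate_id = ids, lcbd = rep(1 / n, n),
                      p_value = NA_real_, p_adjusted = NA_real_,
                      outlier = FALSE, stringsAsFactors = FALSE)
    return(list(table = tab, ss_total = 0, bd_total = 0,
                transform = transform, degenerate = TRUE))
  }
  obs <- ss_i / ss_total
  hits <- rep(0L, n)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      # SS_total is invariant under within-taxon permutation, so the
      # permuted LCBD is just the permuted squared deviations, renormalized
      Sp <- apply(S2, 2, function(col) col[sample.int(n)])
      hits <- hits + (rowSums(Sp) / ss_total >= obs)
    }
  })
  p <- (hits + 1) / (n_perm + 1)
  p_adj <- p.adjust(p, method = "holm")
  tab <- data.frame(replicate_id = ids, lcbd = unname(obs),
                    p_value = p, p_adjusted = p_adj,
                    outlier = p_adj <= alpha, stringsAsFactors = FALSE)
  list(table = tab, ss_total = ss_total, bd_total = ss_total / (n - 1),
       transform = transform, degenerate = FALSE)
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of the squared dissimilarities,
#' `B = -1/2 J D^2 J`, followed by an eigendecomposition.  Coordinates on
#' each axis are the eigenvector scaled by the square root of the absolute
#' eigenvalue.  Non-Euclidean dissimilarities (such as Jaccard) produce
#' negative eigenvalues; those "imaginary" axes are retained separately
#' for dispersion computations while ordination output exposes positive
#' axes only.
#'
#' @param D a `dist` object or symmetric dissimilarity matrix.
#' @return A list of class `replidepth_pcoa`: `points` (positive axes,
#'   replicates x axes), `imaginary_points` (axes for negative
#'   eigenvalues), `eigenvalues` (all, signed, descending), `labels`.
#' @export
pcoa <- function(D) {
  M <- as.matrix(D)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 replicates")
  labs <- rownames(M)
  if (is.null(labs)) labs <- sprintf("obj_%d", seq_len(n))
  A <- -0.5 * M^2
  # double centering: subtract row and column means, add the grand mean
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values), 0) * 1e-9 + 1e-12
  pos <- eig$values > tol
  neg <- eig$values < -tol
  pts <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  imag <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eig$values[neg]), sum(neg))
  rownames(pts) <- rownames(imag) <- labs
  if (ncol(pts) > 0) colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  if (ncol(imag) > 0) colnames(imag) <- sprintf("iPCo%d", seq_len(ncol(imag)))
  structure(list(points = pts, imaginary_points = imag,
                 eigenvalues = eig$values, labels = labs),
            class = "replidepth_pcoa")
}

#' Chi-square test on outlier counts across conditions
#'
#' Pearson chi-square on a contingency table of outlier counts by
#' condition (read sampling depth, minimum read threshold, or extract);
#' the Yates continuity correction is applied for 2x2 tables only.
#'
#' @param counts matrix (>= 2x2) of non-negative integer counts.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
outlier_count_test <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2x2")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(m))   # Yates correction for 2x2 only
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}
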