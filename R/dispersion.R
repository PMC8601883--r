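# Geometric (spatial) median by iteratively reweighted least squares
# (Weiszfeld), started from the centroid.  Points coincident with the
# current iterate get a capped weight so the iteration stays defined.
spatial_median <- function(X, tol = 1e-8, maxit = 1000L) {
  X <- as.matrix(X)
  if (nrow(X) == 1) return(drop(X))
  if (ncol(X) == 0) return(numeric(0))
  m <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    d <- pmax(d, tol)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

# Distances of group members to the group spatial median in PCoA space,
# with the PERMDISP2 correction for non-Euclidean dissimilarities:
# medians are fit separately on real and imaginary axes and the squared
# imaginary distance is subtracted (floored at zero) before the sqrt.
group_median_distances <- function(pts, imag, idx) {
  dr2 <- if (ncol(pts) > 0) {
    med <- spatial_median(pts[idx, , drop = FALSE])
    rowSums(sweep(pts[idx, , drop = FALSE], 2, med)^2)
  } else rep(0, length(idx))
  di2 <- if (ncol(imag) > 0) {
    medi <- spatial_median(imag[idx, , drop = FALSE])
    rowSums(sweep(imag[idx, , drop = FALSE], 2, medi)^2)
  } else rep(0, length(idx))
  sqrt(pmax(dr2 - di2, 0))
}

dispersion_distances <- function(pts, imag, groups, bias_adjust) {
  z <- numeric(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    zg <- group_median_distances(pts, imag, idx)
    if (bias_adjust) zg <- zg * sqrt(length(idx) / (length(idx) - 1))
    z[idx] <- zg
  }
  z
}

anova_f <- function(z, groups) {
  gm <- tapply(z, groups, mean)
  ng <- tapply(z, groups, length)
  ssb <- sum(ng * (gm - mean(z))^2)
  ssw <- sum((z - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(z) - nlevels(groups)
  if (ssw < 1e-12) {
    if (ssb < 1e-12) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

#' Homogeneity of group dispersions around spatial medians
#'
#' A multivariate dispersion (PERMDISP-style) test: replicates are
#' embedded by [pcoa()], each group's spatial median is located
#' (separately on the real and imaginary axes, with the squared imaginary
#' component subtracted from squared distances for non-Euclidean
#' dissimilarities such as Jaccard), and each replicate's
#' distance-to-median is computed.  With `bias_adjust` each group's
#' distances are multiplied by `sqrt(n_g / (n_g - 1))`, correcting the
#' small-sample downward bias.  Group differences in mean dispersion are
#' tested by one-way ANOVA on the distances (parametric F and p), by a
#' permutation of group labels with full recomputation of medians and
#' distances, and pairwise by Tukey HSD.
#'
#' @param D a `dist` object or symmetric dissimilarity matrix.
#' @param groups factor (or vector) of group labels, one per replicate;
#'   singleton groups are excluded with a warning.
#' @param bias_adjust apply the small-sample bias correction
#'   (default `TRUE`).
#' @param n_perm number of label permutations (default 999; `0` skips the
#'   permutation test).
#' @param seed optional integer seed.
#' @return A list of class `beta_dispersion`: `distances` (data.frame
#'   `replicate_id`, `group`, `distance`), `group_means`, `F`,
#'   `p_anova`, `p_permutation`, `df`, `tukey` (data.frame `pair`,
#'   `difference`, `lwr`, `upr`, `p_adjusted`).
#' @export
beta_dispersion <- function(D, groups, bias_adjust = TRUE, n_perm = 999L,
                            seed = NULL) {
  M <- as.matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(M))
    stop("groups must have one label per replicate")
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warning("excluding singleton group(s): ",
            paste(singletons, collapse = ", "))
    keep <- !(groups %in% singletons)
    M <- M[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2")
  ord <- pcoa(M)
  pts <- ord$points
  imag <- ord$imaginary_points
  z <- dispersion_distances(pts, imag, groups, bias_adjust)
  av <- anova_f(z, groups)

  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.finite(av$F) && av$F > 0) {
      exceed <- 0L
      with_seed(seed, {
        for (b in seq_len(n_perm)) {
          gp <- groups[sample.int(length(groups))]
          zp <- dispersion_distances(pts, imag, gp, bias_adjust)
          if (anova_f(zp, gp)$F >= av$F) exceed <- exceed + 1L
        }
      })
      p_perm <- (exceed + 1) / (n_perm + 1)
    } else {
      p_perm <- 1
    }
  }

  tukey <- NULL
  if (av$F > 0 && is.finite(av$F)) {
    df <- data.frame(z = z, g = groups)
    th <- TukeyHSD(aov(z ~ g, data = df))$g
    tukey <- data.frame(pair = rownames(th), difference = th[, "diff"],
                        lwr = th[, "lwr"], upr = th[, "upr"],
                        p_adjusted = th[, "p adj"],
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  labs <- rownames(M)
  if (is.null(labs)) labs <- sprintf("obj_%d", seq_along(z))
  structure(list(
    distances = data.frame(replicate_id = labs, group = groups, distance = z,
                           stringsAsFactors = FALSE),
    group_means = tapply(z, groups, mean),
    F = av$F, p_anova = av$p, p_permutation = p_perm,
    df = c(av$df1, av$df2), tukey = tukey,
    bias_adjust = bias_adjust), class = "beta_dispersion")
}

#' @export
print.beta_dispersion <- function(x, ...) {
  cat(sprintf("beta dispersion: F(%d, %d) = %.4g, ANOVA p = %.4g, permutation p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_anova, x$p_permutation))
  print(round(x$group_means, 4))
  invisible(x)
}
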