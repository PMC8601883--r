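#' Taxon-by-replicate count table
#'
#' The central container of the package: a dense matrix of non-negative
#' integer read counts with one row per taxon and one column per PCR
#' replicate, plus an optional lineage string per taxon.  Lineages are
#' ordered `rank:value` tokens joined by `";"` (e.g.
#' `"family:Poaceae;genus:Stipa"`), so taxa assigned only to genus or
#' family level are representable without padding.
#'
#' @param counts matrix (or data.frame) of non-negative integer counts;
#'   rownames are taxon ids, colnames are replicate ids, both duplicate-free.
#' @param lineage optional character vector of `rank:value;...` strings,
#'   either named by taxon id or in row order; `NA` marks taxa without a
#'   lineage.
#' @return An object of class `taxon_table` with elements `counts` and
#'   `lineage`.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, dimnames = list(c("t1", "t2"), c("r1", "r2")))
#' tt <- taxon_table(m, lineage = c(t1 = "family:Poaceae", t2 = NA))
#' replicate_depths(tt)
#' @export
taxon_table <- function(counts, lineage = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- sprintf("taxon_%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- sprintf("replicate_%d", seq_len(ncol(counts)))
  storage <- counts
  if (!is.integer(storage)) {
    if (any(!is.finite(storage)) || any(storage != round(storage)))
      stop("counts must be whole numbers")
    storage <- matrix(as.integer(round(storage)), nrow(counts),
                      dimnames = dimnames(counts))
  }
  if (anyNA(storage)) stop("counts must not contain missing values")
  if (length(storage) > 0 && any(storage < 0))
    stop("counts must be non-negative")
  if (anyDuplicated(rownames(storage)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(storage)[duplicated(rownames(storage))]), collapse = ", "))
  if (anyDuplicated(colnames(storage)))
    stop("duplicate replicate ids: ",
         paste(unique(colnames(storage)[duplicated(colnames(storage))]), collapse = ", "))
  if (!is.null(lineage)) {
    lineage <- as.character(lineage)
    if (!is.null(names(lineage))) {
      if (!all(names(lineage) %in% rownames(storage)))
        stop("lineage names must be taxon ids")
      full <- setNames(rep(NA_character_, nrow(storage)), rownames(storage))
      full[names(lineage)] <- lineage
      lineage <- full
    } else {
      if (length(lineage) != nrow(storage))
        stop("lineage length must match the number of taxa")
      names(lineage) <- rownames(storage)
    }
  }
  structure(list(counts = storage, lineage = lineage), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d taxa x %d replicates\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts) > 0) {
    d <- replicate_depths(x)
    cat(sprintf("library depths: min %s, median %s, max %s\n",
                format(min(d)), format(stats::median(d)), format(max(d))))
  }
  if (!is.null(x$lineage))
    cat(sprintf("lineage present for %d taxa\n", sum(!is.na(x$lineage))))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Subset a taxon table by taxa and/or replicates
#'
#' @param x a [taxon_table()].
#' @param i,j taxon and replicate indices (names, logical, or integer).
#' @param ... ignored.
#' @export
`[.taxon_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  lineage <- if (is.null(x$lineage)) NULL else x$lineage[rownames(counts)]
  taxon_table(counts, lineage)
}

#' Per-replicate library depths (column sums)
#'
#' @param x a [taxon_table()].
#' @return Named integer vector of total reads per replicate.
#' @export
replicate_depths <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  colSums(x$counts)
}

#' Drop all-zero taxon rows (and optionally empty replicate columns)
#'
#' @param x a [taxon_table()].
#' @param drop_empty_replicates also remove replicate columns whose depth
#'   is zero (default `FALSE`).
#' @return A pruned [taxon_table()]; a 0-taxon table is valid.
#' @examples
#' tt <- taxon_table(matrix(c(0L, 1L, 0L, 1L), 2,
#'                          dimnames = list(c("a", "b"), c("r1", "r2"))))
#' prune_empty(tt)
#' @export
prune_empty <- function(x, drop_empty_replicates = FALSE) {
  stopifnot(inherits(x, "taxon_table"))
  keep_t <- rowSums(x$counts) > 0
  keep_r <- if (drop_empty_replicates) colSums(x$counts) > 0
            else rep(TRUE, ncol(x$counts))
  x[keep_t, keep_r]
}

# Extract the value of one rank from each taxon's lineage tokens; NA when
# the taxon carries no such rank.
lineage_values <- function(x, rank) {
  if (is.null(x$lineage)) return(setNames(rep(NA_character_, nrow(x$counts)),
                                          rownames(x$counts)))
  vapply(x$lineage, function(lin) {
    if (is.na(lin) || !nzchar(lin)) return(NA_character_)
    toks <- strsplit(lin, ";", fixed = TRUE)[[1]]
    kv <- strsplit(toks, ":", fixed = TRUE)
    hit <- vapply(kv, function(p) length(p) >= 2 && p[[1]] == rank, TRUE)
    if (!any(hit)) return(NA_character_)
    paste(kv[[which(hit)[1]]][-1], collapse = ":")
  }, "", USE.NAMES = TRUE)
}

# All rank labels appearing anywhere in the lineage schema.
lineage_ranks <- function(x) {
  if (is.null(x$lineage)) return(character(0))
  lin <- x$lineage[!is.na(x$lineage) & nzchar(x$lineage)]
  toks <- unlist(strsplit(lin, ";", fixed = TRUE), use.names = FALSE)
  unique(vapply(strsplit(toks, ":", fixed = TRUE), `[[`, "", 1L))
}

#' Aggregate taxa at a lineage rank
#'
#' Rows are summed within each value of `rank`; taxa lacking that rank are
#' pooled into an `"unassigned"` row.  With `top_k`, only the `top_k` rank
#' values with the largest total read count keep their own row and the rest
#' are pooled into `"other"` (the relative-abundance barplot convention of
#' showing only the most abundant families).  Per-replicate totals are
#' conserved exactly.
#'
#' @param x a [taxon_table()] with lineage information.
#' @param rank rank label to aggregate at (e.g. `"family"`).
#' @param top_k optional positive integer: keep this many rank values, pool
#'   the rest as `"other"`.
#' @return A [taxon_table()] of aggregated rows.
#' @export
aggregate_by_rank <- function(x, rank, top_k = NULL) {
  stopifnot(inherits(x, "taxon_table"), is.character(rank), length(rank) == 1L)
  ranks <- lineage_ranks(x)
  if (length(ranks) > 0 && !(rank %in% ranks))
    stop("unknown rank label: ", rank)
  vals <- lineage_values(x, rank)
  vals[is.na(vals)] <- "unassigned"
  agg <- rowsum(x$counts, group = vals, reorder = FALSE)
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1)
    totals <- rowSums(agg)
    keep <- rownames(agg)[order(-totals)][seq_len(min(top_k, nrow(agg)))]
    rest <- setdiff(rownames(agg), keep)
    if (length(rest) > 0) {
      pooled <- colSums(agg[rest, , drop = FALSE])
      agg <- rbind(agg[keep, , drop = FALSE], other = pooled)
    }
  }
  lin <- setNames(ifelse(rownames(agg) %in% c("unassigned", "other"),
                         NA_character_, paste0(rank, ":", rownames(agg))),
                  rownames(agg))
  taxon_table(agg, lineage = lin)
}
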