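#' Prevalence-based contaminant scores
#'
#' For each taxon, compares presence/absence across true-sample replicates
#' against the pooled negative controls (extraction and PCR negatives are
#' one "control" class).  The score is a one-sided p-value for enrichment
#' of presence in controls from the 2x2 presence-by-class table: a
#' chi-square test with continuity correction when every expected cell is
#' at least 5, otherwise Fisher's exact test.  Taxa absent from all
#' controls score 1 (cannot be contaminants under a prevalence criterion).
#' A taxon is flagged when its score falls below `threshold` (the
#' convention of prevalence-based decontamination at threshold 0.1).
#'
#' @param x a [taxon_table()].
#' @param meta a [replicate_metadata()] covering every column of `x`.
#' @param threshold flag scores strictly below this value (default 0.1).
#' @return A `data.frame` with columns `taxon_id`, `prevalence_in_samples`,
#'   `prevalence_in_controls`, `score`, `is_contaminant`.
#' @export
prevalence_scores <- function(x, meta, threshold = 0.1) {
  meta <- align_metadata(x, meta)
  is_samp <- meta$sample_type == "sample"
  is_ctrl <- meta$sample_type %in% c("extraction_control", "pcr_control")
  if (!any(is_ctrl))
    stop("no control replicates in metadata; skip decontamination")
  pres <- x$counts > 0
  n_s <- sum(is_samp); n_c <- sum(is_ctrl)
  ps <- rowSums(pres[, is_samp, drop = FALSE])
  pc <- rowSums(pres[, is_ctrl, drop = FALSE])
  score <- vapply(seq_len(nrow(x$counts)), function(i) {
    if (pc[i] == 0) return(1)
    prevalence_test_p(pc[i], n_c, ps[i], n_s)
  }, 0)
  data.frame(taxon_id = rownames(x$counts),
             prevalence_in_samples = unname(ps / n_s),
             prevalence_in_controls = unname(pc / n_c),
             score = score,
             is_contaminant = score < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

# One-sided p for presence being enriched in controls, from the 2x2 table
#   rows: present / absent;  columns: control / sample
prevalence_test_p <- function(pres_ctrl, n_ctrl, pres_samp, n_samp) {
  m <- matrix(c(pres_ctrl, n_ctrl - pres_ctrl,
                pres_samp, n_samp - pres_samp), 2, 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    stat <- suppressWarnings(chisq.test(m, correct = TRUE)$statistic)
    p_two <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (pres_ctrl / n_ctrl > pres_samp / n_samp) unname(p_two / 2)
    else unname(1 - p_two / 2)
  } else {
    # odds ratio > 1 <=> presence enriched in the first (control) column
    fisher.test(m, alternative = "greater")$p.value
  }
}

#' Remove flagged contaminants and control columns
#'
#' Drops every flagged taxon row in full (a contaminant is removed from all
#' replicates, not only controls) and, when metadata is supplied, drops all
#' non-sample columns so downstream analyses see true samples only.
#'
#' @param x a [taxon_table()].
#' @param calls result of [prevalence_scores()] covering all taxa of `x`.
#' @param meta optional [replicate_metadata()]; if given, control and
#'   positive-control columns are removed.
#' @param threshold re-applied flagging threshold (default 0.1).
#' @return The pruned [taxon_table()].
#' @export
remove_contaminants <- function(x, calls, meta = NULL, threshold = 0.1) {
  stopifnot(inherits(x, "taxon_table"))
  if (!all(rownames(x$counts) %in% calls$taxon_id))
    stop("calls must cover every taxon in the table")
  flagged <- calls$taxon_id[calls$score < threshold]
  keep_t <- setdiff(rownames(x$counts), flagged)
  out <- x[keep_t, ]
  if (!is.null(meta)) {
    meta <- align_metadata(x, meta)
    out <- out[, meta$sample_type == "sample"]
  }
  out
}

#' Positive-control index-hop check
#'
#' Counts reads of the spike taxon found outside the positive-control
#' column(s) and foreign (non-spike) reads found inside them.  The hop
#' rate is hopped spike reads over total spike reads; a clean run reports
#' rate 0.
#'
#' @param x a [taxon_table()].
#' @param meta a [replicate_metadata()] with at least one
#'   `positive_control` replicate.
#' @param spike_taxon taxon id of the spike.
#' @return A list: `reads_of_spike_outside_control`,
#'   `foreign_reads_in_control`, `total_spike_reads`, `rate`.
#' @export
index_hop_check <- function(x, meta, spike_taxon) {
  meta <- align_metadata(x, meta)
  if (!spike_taxon %in% rownames(x$counts))
    stop("spike taxon not found in table: ", spike_taxon)
  pos <- meta$sample_type == "positive_control"
  if (!any(pos)) stop("no positive-control replicate in metadata")
  spike <- x$counts[spike_taxon, ]
  outside <- sum(spike[!pos])
  foreign <- sum(x$counts[setdiff(rownames(x$counts), spike_taxon), pos,
                          drop = FALSE])
  total <- sum(spike)
  list(reads_of_spike_outside_control = as.integer(outside),
       foreign_reads_in_control = as.integer(foreign),
       total_spike_reads = as.integer(total),
       rate = if (total > 0) outside / total else 0)
}
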