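#' Read a taxon-by-replicate count table
#'
#' Two on-disk formats are supported.  The canonical format is TSV
#' (UTF-8, header row): first column the taxon id, an optional second
#' column named `lineage` holding semicolon-delimited `rank:value` tokens,
#' and the remaining columns integer read counts headed by replicate ids.
#' `biom_json` is a minimal dense-integer subset of the JSON BIOM 1.0
#' format for interoperability.  Parsing is lossless: writing and
#' re-reading reproduces counts, labels, and lineage exactly.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"biom_json"`.
#' @return A [taxon_table()].
#' @seealso [write_taxon_table()]
#' @export
read_taxon_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_taxon_table_tsv(path) else read_taxon_table_biom(path)
}

read_taxon_table_tsv <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 1) stop("malformed TSV: no columns in ", path)
  taxa <- raw[[1]]
  has_lineage <- ncol(raw) >= 2 && identical(names(raw)[2], "lineage")
  count_cols <- if (has_lineage) seq.int(3, length.out = ncol(raw) - 2)
                else seq.int(2, length.out = ncol(raw) - 1)
  reps <- names(raw)[count_cols]
  counts <- matrix(0L, nrow = nrow(raw), ncol = length(count_cols),
                   dimnames = list(taxa, reps))
  for (j in seq_along(count_cols)) {
    cell <- raw[[count_cols[j]]]
    bad <- !grepl("^[0-9]+$", cell)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("non-integer count '%s' for taxon '%s', replicate '%s'",
                   cell[i], taxa[i], reps[j]))
    }
    counts[, j] <- as.integer(cell)
  }
  lineage <- NULL
  if (has_lineage) {
    lineage <- raw[[2]]
    lineage[lineage == ""] <- NA_character_
    names(lineage) <- taxa
  }
  taxon_table(counts, lineage)
}

read_taxon_table_biom <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(b$matrix_type, "dense"))
    stop("only dense BIOM tables are supported")
  taxa <- vapply(b$rows, function(r) r$id, "")
  reps <- vapply(b$columns, function(cl) cl$id, "")
  counts <- matrix(0L, length(taxa), length(reps),
                   dimnames = list(taxa, reps))
  for (i in seq_along(b$data)) {
    row <- unlist(b$data[[i]])
    if (any(row != round(row)))
      stop(sprintf("non-integer count in BIOM row '%s'", taxa[i]))
    counts[i, ] <- as.integer(row)
  }
  lineage <- vapply(b$rows, function(r) {
    lin <- r$metadata$lineage
    if (is.null(lin)) NA_character_ else paste(unlist(lin), collapse = ";")
  }, "")
  if (all(is.na(lineage))) lineage <- NULL else names(lineage) <- taxa
  taxon_table(counts, lineage)
}

#' Write a taxon-by-replicate count table
#'
#' @param x a [taxon_table()].
#' @param path output file.
#' @param format `"tsv"` (default) or `"biom_json"` (dense-integer JSON
#'   BIOM 1.0 subset).
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(x, path, format = c("tsv", "biom_json")) {
  stopifnot(inherits(x, "taxon_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(x$counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(x$lineage)) {
      lin <- x$lineage
      lin[is.na(lin)] <- ""
      df$lineage <- unname(lin)
    }
    df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rows <- lapply(rownames(x$counts), function(t) {
      lin <- if (is.null(x$lineage) || is.na(x$lineage[[t]])) NULL
             else as.list(strsplit(x$lineage[[t]], ";", fixed = TRUE)[[1]])
      list(id = t, metadata = if (is.null(lin)) NULL else list(lineage = lin))
    })
    cols <- lapply(colnames(x$counts), function(r) list(id = r, metadata = NULL))
    b <- list(
      id = NULL,
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "Taxon table",
      generated_by = "replidepth",
      date = "",
      matrix_type = "dense",
      matrix_element_type = "int",
      shape = dim(x$counts),
      rows = rows,
      columns = cols,
      data = lapply(seq_len(nrow(x$counts)),
                    function(i) as.list(unname(x$counts[i, ])))
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Construct replicate metadata
#'
#' Maps each PCR replicate (column of a [taxon_table()]) to its DNA
#' extract, marker, and sample type.  Sample types follow the control
#' design of a metabarcoding run: true samples, extraction negatives, PCR
#' negatives, and positive (spike-in) controls.
#'
#' @param replicate_id,extract_id,marker character vectors, one entry per
#'   replicate.
#' @param sample_type one of `"sample"`, `"extraction_control"`,
#'   `"pcr_control"`, `"positive_control"` per replicate.
#' @return A `data.frame` of class `replicate_metadata`.
#' @export
replicate_metadata <- function(replicate_id, extract_id, marker, sample_type) {
  sample_type <- as.character(sample_type)
  ok <- sample_type %in% c("sample", "extraction_control", "pcr_control",
                           "positive_control")
  if (!all(ok))
    stop("invalid sample_type: ", paste(unique(sample_type[!ok]), collapse = ", "))
  if (anyDuplicated(replicate_id))
    stop("duplicate replicate ids in metadata")
  out <- data.frame(replicate_id = as.character(replicate_id),
                    extract_id = as.character(extract_id),
                    marker = as.character(marker),
                    sample_type = sample_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("replicate_metadata", "data.frame")
  out
}

#' Read / write replicate metadata TSV
#'
#' The metadata TSV has columns `replicate_id`, `extract_id`, `marker`,
#' `sample_type`.
#'
#' @param path file path.
#' @return [read_replicate_metadata()] returns a [replicate_metadata()]
#'   data frame; the writer returns `path` invisibly.
#' @export
read_replicate_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("replicate_id", "extract_id", "marker", "sample_type")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  replicate_metadata(df$replicate_id, df$extract_id, df$marker, df$sample_type)
}

#' @rdname read_replicate_metadata
#' @param meta a [replicate_metadata()] data frame.
#' @export
write_replicate_metadata <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Check that every replicate column has exactly one metadata record and at
# least one record is a true sample; returns metadata aligned to columns.
align_metadata <- function(x, meta) {
  stopifnot(inherits(x, "taxon_table"))
  reps <- colnames(x$counts)
  miss <- setdiff(reps, meta$replicate_id)
  if (length(miss) > 0)
    stop("replicates missing from metadata: ", paste(miss, collapse = ", "))
  meta <- meta[match(reps, meta$replicate_id), , drop = FALSE]
  if (!any(meta$sample_type == "sample"))
    stop("metadata contains no true-sample replicates")
  meta
}
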