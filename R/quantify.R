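#' Per-sample skipped-isoform percentage
#'
#' Turns junction-read tallies into the per-sample statistic: the percentage
#' of junction evidence supporting the exon-skipped isoform,
#' `100 * n_delta2 / (n_alpha + n_delta2)`. Reads outside the junction
#' (`NON_JUNCTION`) and unresolvable reads (`AMBIGUOUS`) are excluded from
#' the denominator. A sample with no junction reads gets `NA`, never a
#' silent zero. No length normalization is applied: both junction windows
#' have identical width by construction, so the read share estimates the
#' transcript share directly.
#'
#' @param counts A data frame with columns `n_alpha` and `n_delta2` (e.g.
#'   one or more `counts` rows from [classify_sample()], or a
#'   [simulate_counts_cohort()] table).
#' @param min_skip_reads Minimum skip-junction reads for a sample to be
#'   flagged as containing spliced transcripts (default 1).
#'
#' @return The input with columns `n_junction_reads`, `pct_skipped` and
#'   `has_splicing` added.
#' @export
compute_ratio <- function(counts, min_skip_reads = 1L) {
  stopifnot(is.data.frame(counts),
            all(c("n_alpha", "n_delta2") %in% colnames(counts)))
  if (any(counts$n_alpha < 0 | counts$n_delta2 < 0, na.rm = TRUE))
    stop("input error: negative counts", call. = FALSE)
  denom <- counts$n_alpha + counts$n_delta2
  counts$n_junction_reads <- denom
  counts$pct_skipped <- ifelse(denom > 0, 100 * counts$n_delta2 / denom,
                               NA_real_)
  counts$has_splicing <- flag_splicing(counts$n_delta2, min_skip_reads)
  counts
}

#' Flag samples containing skip-junction evidence
#'
#' A sample "contains" exon-skipped transcripts when at least
#' `min_skip_reads` reads support the skip junction; group prevalence is the
#' percentage of flagged samples.
#'
#' @param n_delta2 Skip-junction read count(s).
#' @param min_skip_reads Presence threshold (default 1).
#' @return Logical vector.
#' @export
flag_splicing <- function(n_delta2, min_skip_reads = 1L) {
  stopifnot(min_skip_reads >= 1L)
  n_delta2 >= min_skip_reads
}

#' De-identify a cohort table
#'
#' Replaces original sample identifiers by sequential numbers assigned in a
#' seeded random order, and replaces any nucleotide-sequence columns by runs
#' of `N` of equal length. The original-to-new mapping is never stored in
#' the table; it can optionally be written to a separate file.
#'
#' @param table Data frame with a `sample_id` column of original identifiers.
#' @param seed Integer seed for the shuffled assignment.
#' @param id_map_path Optional path; when given, the mapping TSV
#'   (`original_id`, `new_id`) is written there and nowhere else.
#' @param sequence_cols Character vector of columns to mask with `N` runs.
#'
#' @return The table with `sample_id` replaced by the unlinked numbers (rows
#'   re-ordered by new id) and sequence columns masked.
#' @export
deidentify <- function(table, seed = 1L, id_map_path = NULL,
                       sequence_cols = NULL) {
  stopifnot(is.data.frame(table), "sample_id" %in% colnames(table))
  if (anyDuplicated(table$sample_id))
    stop("input error: duplicate sample ids", call. = FALSE)
  n <- nrow(table)
  if (n > 0L) {
    set.seed(seed)
    new_id <- sample.int(n)
    if (!is.null(id_map_path))
      .write_tsv(data.frame(original_id = table$sample_id, new_id = new_id,
                            stringsAsFactors = FALSE),
                 id_map_path, provenance = "de-identification map -- do not distribute")
    table$sample_id <- new_id
    table <- table[order(table$sample_id), , drop = FALSE]
    rownames(table) <- NULL
  }
  for (col in sequence_cols) {
    if (!col %in% colnames(table))
      stop("input error: no column named ", col, call. = FALSE)
    table[[col]] <- strrep("N", nchar(table[[col]]))
  }
  table
}

#' Write the de-identified cohort summary
#'
#' Tab-delimited, UTF-8, Unix newlines; provenance as leading `#` comment
#' lines; deterministic column order; `NA` rendered literally; percentages
#' rendered with four decimals.
#'
#' @param table Cohort table (after [compute_ratio()] and [deidentify()]).
#' @param path Output path.
#' @param provenance Character vector of provenance lines (written as
#'   `#` comments).
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path, provenance = NULL) {
  cols <- c("sample_id", "group", "sex", "apoe", "n_alpha", "n_delta2",
            "n_junction_reads", "pct_skipped", "has_splicing")
  cols <- c(intersect(cols, colnames(table)),
            setdiff(colnames(table), cols))
  out <- table[, cols, drop = FALSE]
  if ("pct_skipped" %in% colnames(out))
    out$pct_skipped <- ifelse(is.na(out$pct_skipped), NA,
                              sprintf("%.4f", out$pct_skipped))
  .write_tsv(out, path, provenance = provenance %||%
               sprintf("baxsplice %s cohort summary",
                       as.character(utils::packageVersion("baxsplice"))))
  invisible(path)
}

#' Read back a cohort summary written by [write_summary()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_summary <- function(path) {
  out <- .read_tsv(path)
  if ("has_splicing" %in% colnames(out))
    out$has_splicing <- as.logical(out$has_splicing)
  out
}
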