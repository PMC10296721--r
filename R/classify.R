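#' Classify reads by competitive alignment to the two isoform references
#'
#' Each read is aligned locally to the canonical and the exon-skipped
#' reference (both orientations by default) and assigned one of four call
#' classes: `ALPHA` (canonical junction), `DELTA2` (skip junction),
#' `AMBIGUOUS` (both references satisfy the junction rule with equal score),
#' or `NON_JUNCTION` (neither satisfies it; this includes reads from shared
#' exons that never cross the diagnostic window). The satisfying reference
#' with the strictly higher alignment score wins; ties are never broken
#' arbitrarily.
#'
#' @param reads A data frame with `read_id` and `sequence` columns, a named
#'   character vector, or a `Biostrings::DNAStringSet`.
#' @param pair An isoform pair with its junction window set
#'   ([set_junction_window()]).
#' @param params A [classifier_params()].
#'
#' @return A data frame with one row per read: `read_id`, `call`,
#'   `winning_score`, `margin` (winner minus runner-up score, 0-floored at
#'   `NA` for `NON_JUNCTION`), the per-reference scores, and the winning
#'   alignment's coordinates/orientation/CIGAR (for SAM export).
#' @export
classify_reads <- function(reads, pair, params = classifier_params()) {
  stopifnot(inherits(pair, "isoform_pair"))
  if (is.null(pair$window))
    stop("configuration error: the isoform pair has no junction window; call set_junction_window()",
         call. = FALSE)
  reads <- .as_read_frame(reads)
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(read_id = character(), call = character(),
                      winning_score = numeric(), margin = numeric(),
                      score_canonical = numeric(), score_skipped = numeric(),
                      reference = character(), ref_start = integer(),
                      ref_end = integer(), strand = character(),
                      cigar = character(), n_mismatch = integer(),
                      n_gap = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }

  ev_c <- .align_evaluate(reads$sequence, pair$canonical$sequence,
                          pair$junction_pos_canonical, pair$window, params)
  ev_s <- .align_evaluate(reads$sequence, pair$skipped$sequence,
                          pair$junction_pos_skipped, pair$window, params)
  out <- .resolve_calls(reads$read_id, ev_c, ev_s)
  out$sequence <- reads$sequence
  out
}

.resolve_calls <- function(read_id, ev_c, ev_s) {
  n <- length(read_id)
  call <- rep("NON_JUNCTION", n)
  winning <- rep(NA_real_, n)
  margin <- rep(NA_real_, n)
  reference <- rep(NA_character_, n)

  both <- ev_c$satisfies & ev_s$satisfies
  only_c <- ev_c$satisfies & !ev_s$satisfies
  only_s <- ev_s$satisfies & !ev_c$satisfies

  call[only_c] <- "ALPHA"
  call[only_s] <- "DELTA2"
  call[both & ev_c$score > ev_s$score] <- "ALPHA"
  call[both & ev_s$score > ev_c$score] <- "DELTA2"
  call[both & ev_c$score == ev_s$score] <- "AMBIGUOUS"

  is_a <- call == "ALPHA"
  is_d <- call == "DELTA2"
  winning[is_a] <- ev_c$score[is_a]
  winning[is_d] <- ev_s$score[is_d]
  winning[call == "AMBIGUOUS"] <- ev_c$score[call == "AMBIGUOUS"]
  # margin: winner minus the best other *satisfying* score (0 when none)
  margin[is_a] <- ev_c$score[is_a] - ifelse(both[is_a], ev_s$score[is_a], 0)
  margin[is_d] <- ev_s$score[is_d] - ifelse(both[is_d], ev_c$score[is_d], 0)
  margin[call == "AMBIGUOUS"] <- 0

  reference[is_a] <- "canonical"
  reference[is_d] <- "skipped"
  pick <- function(field) {
    out <- rep(NA, n)
    out[is_a] <- ev_c[[field]][is_a]
    out[is_d] <- ev_s[[field]][is_d]
    out
  }
  data.frame(read_id = read_id, call = call, winning_score = winning,
             margin = margin, score_canonical = ev_c$score,
             score_skipped = ev_s$score, reference = reference,
             ref_start = as.integer(pick("ref_start")),
             ref_end = as.integer(pick("ref_end")),
             strand = as.character(pick("strand")),
             cigar = as.character(pick("cigar")),
             n_mismatch = as.integer(pick("n_mismatch")),
             n_gap = as.integer(pick("n_gap")),
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads
#' @param read_sequence A single read sequence.
#' @param read_id Read identifier for the returned record.
#' @export
classify_read <- function(read_sequence, pair, params = classifier_params(),
                          read_id = "read") {
  classify_reads(stats::setNames(as.character(read_sequence), read_id),
                 pair, params)
}

.as_read_frame <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = as.character(reads),
                      stringsAsFactors = FALSE))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = unname(reads),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in%
                                        colnames(reads)))
  if (anyDuplicated(reads$read_id))
    stop("input error: duplicate read_id values", call. = FALSE)
  reads[, c("read_id", "sequence")]
}

#' Classify a whole sample and tally call classes
#'
#' Runs [classify_reads()] (or the SAM/BAM ingestion path) over all reads of
#' one sample and returns the per-class tallies that feed the skipped-isoform
#' percentage. Paired-end mates (`.../1`, `.../2` read ids) are classified
#' independently and merged to one call per fragment: agreeing mates (or one
#' informative mate) keep the informative call, conflicting isoform calls
#' become `AMBIGUOUS`.
#'
#' @param reads_source A FASTQ path, a SAM/BAM path, or any `reads` object
#'   accepted by [classify_reads()].
#' @param pair An isoform pair with its window set.
#' @param params A [classifier_params()].
#' @param sample_id Sample label for the counts row.
#' @param format `"auto"` (by file extension), `"fastq"`, or `"sam"`.
#' @param audit_path Optional path; when given, per-read calls are written
#'   there as a TSV audit file.
#'
#' @return A list with `counts` (one-row data frame: `sample_id`, `n_alpha`,
#'   `n_delta2`, `n_ambiguous`, `n_nonjunction`, `n_total`) and `calls` (the
#'   per-read/per-fragment call table).
#' @export
classify_sample <- function(reads_source, pair, params = classifier_params(),
                            sample_id = "sample",
                            format = c("auto", "fastq", "sam"),
                            audit_path = NULL) {
  format <- match.arg(format)
  if (is.character(reads_source) && length(reads_source) == 1L &&
      is.null(names(reads_source)) &&
      (format != "auto" || grepl("\\.(fastq|fq|sam|bam)(\\.gz)?$",
                                 reads_source, ignore.case = TRUE))) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", reads_source)))
    format <- if (format != "auto") format
              else if (ext %in% c("fastq", "fq")) "fastq" else "sam"
    calls <- if (format == "fastq") {
      fq <- Biostrings::readDNAStringSet(reads_source, format = "fastq")
      classify_reads(fq, pair, params)
    } else {
      .classify_sam(reads_source, pair, params)
    }
  } else {
    calls <- classify_reads(reads_source, pair, params)
  }

  calls <- .merge_mate_calls(calls)
  counts <- data.frame(
    sample_id = sample_id,
    n_alpha = sum(calls$call == "ALPHA"),
    n_delta2 = sum(calls$call == "DELTA2"),
    n_ambiguous = sum(calls$call == "AMBIGUOUS"),
    n_nonjunction = sum(calls$call == "NON_JUNCTION"),
    n_total = nrow(calls),
    stringsAsFactors = FALSE)
  if (!is.null(audit_path))
    .write_tsv(calls[, c("read_id", "call", "winning_score", "margin")],
               audit_path,
               provenance = sprintf("per-read junction calls sample=%s",
                                    sample_id))
  list(counts = counts, calls = calls)
}

# one call per fragment: informative call wins over NON_JUNCTION;
# conflicting ALPHA/DELTA2 mates -> AMBIGUOUS
.merge_mate_calls <- function(calls) {
  mate <- grepl("/[12]$", calls$read_id)
  if (!any(mate)) return(calls)
  singles <- calls[!mate, , drop = FALSE]
  m <- calls[mate, , drop = FALSE]
  frag <- sub("/[12]$", "", m$read_id)
  merged <- lapply(split(seq_len(nrow(m)), factor(frag, levels = unique(frag))),
                   function(i) {
    d <- m[i, , drop = FALSE]
    informative <- d[d$call %in% c("ALPHA", "DELTA2"), , drop = FALSE]
    if (nrow(informative) == 0L) {
      row <- d[1L, , drop = FALSE]
      row$call <- if (any(d$call == "AMBIGUOUS")) "AMBIGUOUS" else "NON_JUNCTION"
    } else if (length(unique(informative$call)) == 1L) {
      row <- informative[which.max(informative$winning_score), , drop = FALSE]
    } else {
      row <- informative[1L, , drop = FALSE]
      row$call <- "AMBIGUOUS"
    }
    row$read_id <- sub("/[12]$", "", row$read_id)
    row
  })
  out <- rbind(singles, do.call(rbind, merged))
  rownames(out) <- NULL
  out
}
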