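#' Exon model of a transcript
#'
#' An exon model couples a transcript sequence with an ordered set of exon
#' intervals that tile it exactly. Coordinates are 1-based inclusive on the
#' transcript (not the genome), matching how junction windows are specified
#' in reports and configuration.
#'
#' @param sequence Nucleotide sequence over `{A,C,G,T,N}` as a single string
#'   (or a Biostrings `XString`). Lowercase is accepted and upper-cased;
#'   `U` is converted to `T`.
#' @param exons A data frame with columns `exon_label`, `start`, `end`
#'   (1-based inclusive), or a two-column numeric frame/matrix in which case
#'   labels `E1, E2, ...` are assigned. Exons must be sorted, non-overlapping
#'   and contiguous: together they must tile the sequence exactly.
#' @param transcript_id Label used as the reference name in alignments and
#'   SAM output.
#'
#' @return An object of class `exon_model`: a list with elements
#'   `transcript_id`, `sequence` and `exons`.
#'
#' @examples
#' m <- exon_model("ACGTACGTACGGGGCCCCTTAATTAA",
#'                 data.frame(exon_label = c("E1", "E2", "E3"),
#'                            start = c(1, 11, 19), end = c(10, 18, 26)))
#' exon_lengths(m)
#' @export
exon_model <- function(sequence, exons, transcript_id = "transcript") {
  sequence <- .normalize_sequence(sequence)
  exons <- .normalize_exons(exons)
  n <- nchar(sequence)

  if (exons$start[1L] > 1L)
    stop(sprintf("model error: gap at base 1 (first exon '%s' starts at %d)",
                 exons$exon_label[1L], exons$start[1L]), call. = FALSE)
  if (nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      nxt <- exons$start[i + 1L]
      end <- exons$end[i]
      if (nxt > end + 1L)
        stop(sprintf("model error: gap at base %d (between exons '%s' and '%s')",
                     end + 1L, exons$exon_label[i], exons$exon_label[i + 1L]),
             call. = FALSE)
      if (nxt <= end)
        stop(sprintf("model error: overlap at base %d (exons '%s' and '%s')",
                     nxt, exons$exon_label[i], exons$exon_label[i + 1L]),
             call. = FALSE)
    }
  }
  last <- exons$end[nrow(exons)]
  if (last < n)
    stop(sprintf("model error: gap at base %d (exons end before sequence does)",
                 last + 1L), call. = FALSE)
  if (last > n)
    stop(sprintf("model error: exon '%s' extends to base %d beyond the %d-base sequence",
                 exons$exon_label[nrow(exons)], last, n), call. = FALSE)

  structure(list(transcript_id = transcript_id, sequence = sequence,
                 exons = exons),
            class = "exon_model")
}

.normalize_exons <- function(exons) {
  if (is.matrix(exons)) exons <- as.data.frame(exons)
  stopifnot(is.data.frame(exons), nrow(exons) >= 1L)
  cols <- tolower(colnames(exons))
  if (all(c("exon_label", "start_1based", "end_1based") %in% cols)) {
    exons <- data.frame(exon_label = as.character(exons[[which(cols == "exon_label")]]),
                        start = as.integer(exons[[which(cols == "start_1based")]]),
                        end = as.integer(exons[[which(cols == "end_1based")]]),
                        stringsAsFactors = FALSE)
  } else if (all(c("start", "end") %in% cols)) {
    lab <- if ("exon_label" %in% cols) as.character(exons[[which(cols == "exon_label")]])
           else paste0("E", seq_len(nrow(exons)))
    exons <- data.frame(exon_label = lab,
                        start = as.integer(exons[[which(cols == "start")]]),
                        end = as.integer(exons[[which(cols == "end")]]),
                        stringsAsFactors = FALSE)
  } else if (ncol(exons) == 2L) {
    exons <- data.frame(exon_label = paste0("E", seq_len(nrow(exons))),
                        start = as.integer(exons[[1L]]),
                        end = as.integer(exons[[2L]]),
                        stringsAsFactors = FALSE)
  } else {
    stop("exons must have columns (exon_label, start, end) or (exon_label, start_1based, end_1based)",
         call. = FALSE)
  }
  if (anyNA(exons$start) || anyNA(exons$end))
    stop("model error: non-numeric exon coordinates", call. = FALSE)
  if (any(exons$start > exons$end))
    stop(sprintf("model error: exon '%s' has start > end",
                 exons$exon_label[which(exons$start > exons$end)[1L]]),
         call. = FALSE)
  if (is.unsorted(exons$start, strictly = TRUE))
    stop("model error: exons are not sorted by start", call. = FALSE)
  rownames(exons) <- NULL
  exons
}

#' Load a transcript reference and its exon model from files
#'
#' Reads a single-record FASTA (or a named record from a multi-record file)
#' and an exon-interval table, and returns a validated [exon_model()].
#'
#' @param fasta_path Path to a FASTA file.
#' @param exon_intervals Either a data frame accepted by [exon_model()] or the
#'   path to a tab-delimited file with columns
#'   `exon_label`, `start_1based`, `end_1based`.
#' @param record Optional name of the FASTA record to use when the file holds
#'   more than one sequence.
#' @param transcript_id Reference label; defaults to the FASTA record name.
#'
#' @return An [exon_model()].
#' @export
load_reference <- function(fasta_path, exon_intervals, record = NULL,
                           transcript_id = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L)
    stop("input error: no sequence records in ", fasta_path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(seqs))
  if (!is.null(record)) {
    hit <- which(nms == record)
    if (length(hit) != 1L)
      stop(sprintf("input error: record '%s' not found in %s (records: %s)",
                   record, fasta_path, paste(nms, collapse = ", ")),
           call. = FALSE)
    seqs <- seqs[hit]
    nms <- nms[hit]
  } else if (length(seqs) > 1L) {
    stop(sprintf("input error: %s holds %d records; name one via `record`",
                 fasta_path, length(seqs)), call. = FALSE)
  }
  if (is.character(exon_intervals) && length(exon_intervals) == 1L)
    exon_intervals <- utils::read.delim(exon_intervals,
                                        stringsAsFactors = FALSE)
  exon_model(as.character(seqs[[1L]]), exon_intervals,
             transcript_id = transcript_id %||% nms[1L])
}

#' @export
print.exon_model <- function(x, ...) {
  cat(sprintf("exon_model '%s': %d nt, %d exon(s)\n",
              x$transcript_id, nchar(x$sequence), nrow(x$exons)))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' @rdname exon_model
#' @param model An `exon_model`.
#' @export
exon_lengths <- function(model) {
  stopifnot(inherits(model, "exon_model"))
  stats::setNames(model$exons$end - model$exons$start + 1L,
                  model$exons$exon_label)
}
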