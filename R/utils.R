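`%||%` <- function(x, y) if (is.null(x)) y else x

.normalize_sequence <- function(sequence) {
  if (inherits(sequence, "XString") || inherits(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("u", "t", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (!nzchar(sequence))
    stop("input error: empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("input error: sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  sequence
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# number of entries of each element of `pos_list` falling in [w1, w2];
# vectorized over the list to stay cheap on large read batches
.count_in_window <- function(pos_list, w1, w2) {
  len <- lengths(pos_list)
  out <- integer(length(pos_list))
  if (sum(len) == 0L) return(out)
  idx <- rep.int(seq_along(pos_list), len)
  pos <- unlist(pos_list, use.names = FALSE)
  keep <- pos >= w1 & pos <= w2
  if (any(keep)) {
    tab <- tabulate(idx[keep], nbins = length(pos_list))
    out <- tab
  }
  out
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con, sep = "\n")
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
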