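# SAM/BAM ingestion and export against the two isoform references.
# Ingestion keeps only mapped, primary records (FLAG bits 0x4 and 0x100
# unset, i.e. the `samtools view -F 256` filter plus the mapped requirement).

.cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*")
      return(list(len = integer(), op = character()))
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    list(len = len, op = op)
  })
}

.cigar_ref_width <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# reference positions consumed by M/=/X ops, in order (the bases MD's
# match/mismatch tokens walk over)
.cigar_match_refpos <- function(pos, ops) {
  refpos <- integer(0)
  at <- pos
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      refpos <- c(refpos, seq.int(at, length.out = len))
      at <- at + len
    } else if (op %in% c("D", "N")) {
      at <- at + len
    }
  }
  refpos
}

# mismatch reference positions from an MD tag
.md_mismatch_positions <- function(pos, ops, md) {
  mpos <- .cigar_match_refpos(pos, ops)
  tokens <- regmatches(md, gregexpr("[0-9]+|\\^[A-Zn]+|[A-Zn]", md))[[1L]]
  idx <- 0L
  out <- integer(0)
  for (tk in tokens) {
    if (grepl("^[0-9]+$", tk)) {
      idx <- idx + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      # deleted reference bases: not part of the matched-base walk
    } else {
      idx <- idx + 1L
      out <- c(out, mpos[idx])
    }
  }
  out
}

# mismatch reference positions by direct comparison of SEQ with the
# reference along the CIGAR (N in either sequence counts as mismatch)
.compare_mismatch_positions <- function(pos, ops, seq, ref_seq) {
  out <- integer(0)
  at_ref <- pos
  at_read <- 1L
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      rd <- strsplit(substr(seq, at_read, at_read + len - 1L), "")[[1L]]
      rf <- strsplit(substr(ref_seq, at_ref, at_ref + len - 1L), "")[[1L]]
      bad <- rd != rf | rd == "N" | rf == "N"
      out <- c(out, (seq.int(at_ref, length.out = len))[bad])
      at_ref <- at_ref + len
      at_read <- at_read + len
    } else if (op %in% c("D", "N")) {
      at_ref <- at_ref + len
    } else if (op %in% c("I", "S")) {
      at_read <- at_read + len
    }
  }
  out
}

#' Ingest primary alignments from a SAM/BAM file
#'
#' Reads alignments against the two isoform references, keeping only mapped
#' primary records (FLAG bit 0x100 unset and 0x4 unset -- the
#' `samtools view -F 256` filter on mapped reads). Mismatch positions are
#' taken from the MD tag when present, otherwise recomputed by comparing the
#' stored sequence with the reference; records with neither carry the NM
#' total only, and a record with no usable mismatch information is flagged
#' so classification can fall back to `AMBIGUOUS`.
#'
#' @param sam_or_bam_path Path to a SAM or BAM file whose reference names
#'   match the pair's transcript ids.
#' @param pair The isoform pair the file was aligned against.
#'
#' @return A data frame with one row per kept record: `read_id`,
#'   `reference` (`"canonical"`/`"skipped"`), `ref_start`, `ref_end`,
#'   `strand`, `cigar`, `nm`, plus list-columns `mismatch_pos`, `del_pos`,
#'   `ins_pos` (reference coordinates) and `mm_known`.
#' @export
ingest_sam <- function(sam_or_bam_path, pair) {
  stopifnot(inherits(pair, "isoform_pair"))
  path <- sam_or_bam_path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]

  n <- length(res$qname)
  ids <- c(canonical = pair$canonical$transcript_id,
           skipped = pair$skipped$transcript_id)
  empty <- data.frame(read_id = character(), reference = character(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), cigar = character(),
                      nm = integer(), stringsAsFactors = FALSE)
  if (n == 0L) {
    empty$mismatch_pos <- list(); empty$del_pos <- list()
    empty$ins_pos <- list(); empty$mm_known <- logical()
    return(empty)
  }

  rname <- as.character(res$rname)
  unknown <- setdiff(unique(rname), ids)
  if (length(unknown))
    stop(sprintf("input error: unknown reference name(s) %s; expected %s",
                 paste(unknown, collapse = ", "),
                 paste(ids, collapse = ", ")), call. = FALSE)
  reference <- names(ids)[match(rname, ids)]
  ops_list <- .cigar_ops(res$cigar)
  ref_end <- res$pos +
    vapply(ops_list, .cigar_ref_width, integer(1L)) - 1L
  seqs <- as.character(res$seq)
  md <- res$tag$MD %||% rep(NA_character_, n)
  nm <- res$tag$NM %||% rep(NA_integer_, n)

  mismatch_pos <- vector("list", n)
  del_pos <- vector("list", n)
  ins_pos <- vector("list", n)
  mm_known <- logical(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    ops <- ops_list[[i]]
    # reference coordinates of deletions / insertion breakpoints
    at <- res$pos[i]
    dp <- integer(0); ip <- integer(0)
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) at <- at + len
      else if (op %in% c("D", "N")) { dp <- c(dp, seq.int(at, length.out = len)); at <- at + len }
      else if (op == "I") ip <- c(ip, at - 1L)
    }
    del_pos[[i]] <- dp
    ins_pos[[i]] <- ip
    ref_seq <- pair[[reference[i]]]$sequence
    if (!is.na(md[i])) {
      mismatch_pos[[i]] <- .md_mismatch_positions(res$pos[i], ops, md[i])
      mm_known[i] <- TRUE
    } else if (!is.na(seqs[i]) && seqs[i] != "" && seqs[i] != "*") {
      mismatch_pos[[i]] <- .compare_mismatch_positions(res$pos[i], ops,
                                                       seqs[i], ref_seq)
      mm_known[i] <- TRUE
    } else if (!is.na(nm[i])) {
      mismatch_pos[[i]] <- integer(0)
      # NM gives the total only; zero means no mismatches anywhere, which is
      # fully informative -- positive totals leave the window count unknown
      mm_known[i] <- nm[i] == 0L
      if (!mm_known[i] && !warned) {
        warning("records without MD tag or sequence: per-window mismatch positions unknown",
                call. = FALSE)
        warned <- TRUE
      }
    } else {
      mismatch_pos[[i]] <- integer(0)
      mm_known[i] <- FALSE
      if (!warned) {
        warning("records without NM/MD tag or sequence: mismatches unknown",
                call. = FALSE)
        warned <- TRUE
      }
    }
  }

  out <- data.frame(read_id = res$qname, reference = reference,
                    ref_start = res$pos, ref_end = ref_end,
                    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
                    cigar = res$cigar, nm = as.integer(nm),
                    stringsAsFactors = FALSE)
  out$mismatch_pos <- mismatch_pos
  out$del_pos <- del_pos
  out$ins_pos <- ins_pos
  out$mm_known <- mm_known
  out
}

# Classification from ingested SAM records. Scores are reconstructed from
# the alignment runs under the scoring scheme so the competitive comparison
# matches the internal-aligner path.
.classify_sam <- function(path, pair, params) {
  rec <- ingest_sam(path, pair)
  read_ids <- unique(rec$read_id)
  n <- length(read_ids)

  eval_ref <- function(refname) {
    junction <- if (refname == "canonical") pair$junction_pos_canonical
                else pair$junction_pos_skipped
    sub <- rec[rec$reference == refname, , drop = FALSE]
    idx <- match(read_ids, sub$read_id)
    template <- list(score = rep(0, n),
                     ref_start = rep(0L, n), ref_end = rep(0L, n),
                     read_start = rep(0L, n), read_end = rep(0L, n),
                     n_mismatch = rep(0L, n), n_ins = rep(0L, n),
                     n_del = rep(0L, n),
                     mismatch_pos = rep(list(integer(0)), n),
                     del_pos = rep(list(integer(0)), n),
                     ins_pos = rep(list(integer(0)), n),
                     cigar = rep("*", n))
    hit <- !is.na(idx)
    if (any(hit)) {
      h <- idx[hit]
      template$ref_start[hit] <- sub$ref_start[h]
      template$ref_end[hit] <- sub$ref_end[h]
      template$cigar[hit] <- sub$cigar[h]
      template$mismatch_pos[hit] <- sub$mismatch_pos[h]
      template$del_pos[hit] <- sub$del_pos[h]
      template$ins_pos[hit] <- sub$ins_pos[h]
      ops <- .cigar_ops(sub$cigar[h])
      n_aligned <- vapply(ops, function(o) sum(o$len[o$op %in% c("M", "=", "X")]),
                          numeric(1L))
      gap_runs <- lapply(ops, function(o) o$len[o$op %in% c("I", "D")])
      nmm <- ifelse(sub$mm_known[h], lengths(sub$mismatch_pos[h]),
                    pmax(sub$nm[h] - vapply(gap_runs, sum, numeric(1L)), 0L))
      template$n_mismatch[hit] <- as.integer(nmm)
      template$score[hit] <- params$match_score * (n_aligned - nmm) +
        params$mismatch_penalty * nmm +
        vapply(gap_runs, function(g)
          sum(params$gap_open + g * params$gap_extend), numeric(1L))
    }
    ev <- .evaluate_junction_rule(template, junction, pair$window, params,
                                  strand = ifelse(hit, sub$strand[idx], "+"))
    # record present but per-window mismatch positions unknown: the rule can
    # be neither confirmed nor refuted for this reference
    ev$mm_unknown <- hit & !ifelse(hit, sub$mm_known[idx], TRUE)
    ev
  }

  ev_c <- eval_ref("canonical")
  ev_s <- eval_ref("skipped")
  out <- .resolve_calls(read_ids, ev_c, ev_s)
  # a read whose only evidence passes every structural criterion but whose
  # window mismatches are unknown cannot be assigned: class AMBIGUOUS
  force_amb <- (ev_c$mm_unknown & ev_c$satisfies) |
    (ev_s$mm_unknown & ev_s$satisfies)
  out$call[force_amb] <- "AMBIGUOUS"
  out$sequence <- NA_character_
  out
}

#' Write classified junction reads to SAM
#'
#' Exports the winning alignments of junction reads (`ALPHA`/`DELTA2` calls)
#' as a SAM file against the two references, with NM and MD tags, matching
#' the subsetting step of the original analysis. With
#' `mask_sequences = TRUE` every SEQ field is replaced by an equal-length
#' run of `N`, the de-identification applied before such files are shared.
#'
#' @param calls The `calls` data frame from [classify_sample()] (internal
#'   aligner path; it must carry sequences).
#' @param pair The isoform pair.
#' @param path Output SAM path.
#' @param mask_sequences Replace read sequences by `N` runs.
#'
#' @return `path`, invisibly.
#' @export
write_sam <- function(calls, pair, path, mask_sequences = FALSE) {
  stopifnot(inherits(pair, "isoform_pair"))
  keep <- calls[calls$call %in% c("ALPHA", "DELTA2"), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", pair$canonical$transcript_id,
                   nchar(pair$canonical$sequence)),
           sprintf("@SQ\tSN:%s\tLN:%d", pair$skipped$transcript_id,
                   nchar(pair$skipped$sequence)),
           "@PG\tID:baxsplice\tPN:baxsplice")
  lines <- character(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    r <- keep[i, ]
    ref_model <- pair[[r$reference]]
    seq_out <- r$sequence
    if (is.na(seq_out)) seq_out <- "*"
    flag <- 0L
    if (!is.na(r$strand) && r$strand == "-") {
      flag <- 16L
      if (seq_out != "*") seq_out <- .revcomp(seq_out)
    }
    ops <- .cigar_ops(r$cigar)[[1L]]
    md <- ""
    nm <- r$n_mismatch + sum(ops$len[ops$op %in% c("I", "D")])
    if (seq_out != "*") {
      md <- .md_string(r$ref_start, ops, seq_out, ref_model$sequence)
      qual <- strrep("I", nchar(seq_out))
      if (mask_sequences) seq_out <- strrep("N", nchar(seq_out))
    } else {
      qual <- "*"
    }
    tags <- sprintf("NM:i:%d", nm)
    if (nzchar(md)) tags <- paste(tags, sprintf("MD:Z:%s", md), sep = "\t")
    lines[i] <- paste(r$read_id, flag, ref_model$transcript_id, r$ref_start,
                      60L, r$cigar, "*", 0L, 0L, seq_out, qual, tags,
                      sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

# MD tag from SEQ vs reference along the CIGAR
.md_string <- function(pos, ops, seq, ref_seq) {
  out <- character(0)
  run <- 0L
  at_ref <- pos; at_read <- 1L
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      rd <- strsplit(substr(seq, at_read, at_read + len - 1L), "")[[1L]]
      rf <- strsplit(substr(ref_seq, at_ref, at_ref + len - 1L), "")[[1L]]
      for (b in seq_len(len)) {
        if (rd[b] == rf[b]) run <- run + 1L
        else { out <- c(out, as.character(run), rf[b]); run <- 0L }
      }
      at_ref <- at_ref + len; at_read <- at_read + len
    } else if (op %in% c("D", "N")) {
      out <- c(out, as.character(run),
               paste0("^", substr(ref_seq, at_ref, at_ref + len - 1L)))
      run <- 0L
      at_ref <- at_ref + len
    } else if (op %in% c("I", "S")) {
      at_read <- at_read + len
    }
  }
  paste0(paste(out, collapse = ""), run)
}
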