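#' Classifier parameters
#'
#' Scoring and junction-rule thresholds for competitive read classification.
#' A reference "satisfies the junction rule" for a read when the read's best
#' local alignment to it (i) covers the diagnostic window (`full_window`) or
#' overlaps it (`any_overlap`), (ii) is gapless inside the window, (iii) has
#' at least `min_anchor` aligned bases on each side of that reference's
#' junction position, and (iv) has at most `max_mismatch_in_window`
#' mismatches inside the window. Defaults are chosen so that one sequencing
#' error can never flip a read from one isoform's junction to the other's:
#' the two junction k-mers differ by at least `min_anchor` bases.
#'
#' @param match_score Positive score for a match. `N` never scores as a
#'   match, in either sequence.
#' @param mismatch_penalty Non-positive mismatch score.
#' @param gap_open,gap_extend Non-positive affine gap penalties; a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @param min_anchor Minimum aligned bases required on each side of the
#'   junction.
#' @param max_mismatch_in_window Mismatches tolerated inside the window.
#' @param overlap_mode `"full_window"` (alignment must cover the whole
#'   window; default) or `"any_overlap"`.
#' @param both_strands Try the reverse complement of each read as well and
#'   keep the better orientation (forward wins ties).
#'
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(match_score = 2, mismatch_penalty = -3,
                              gap_open = -5, gap_extend = -2,
                              min_anchor = 5L, max_mismatch_in_window = 1L,
                              overlap_mode = c("full_window", "any_overlap"),
                              both_strands = TRUE) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(match_score > 0, mismatch_penalty <= 0, gap_open <= 0,
            gap_extend <= 0, min_anchor >= 1L, max_mismatch_in_window >= 0L)
  structure(list(match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_anchor = as.integer(min_anchor),
                 max_mismatch_in_window = as.integer(max_mismatch_in_window),
                 overlap_mode = overlap_mode,
                 both_strands = isTRUE(both_strands)),
            class = "classifier_params")
}

#' Local alignment of a read against a reference
#'
#' Optimal affine-gap local alignment (Smith-Waterman-Gotoh) with fully
#' deterministic tie-breaking: the traceback prefers a diagonal move over a
#' gap in the read over a gap in the reference, and among equal-scoring end
#' cells the smallest reference, then read, coordinate wins. `N` never
#' scores as a match. An empty or unalignable read yields a score-0 record.
#'
#' @param read_sequence Read sequence (string).
#' @param reference_sequence Reference sequence (string or [exon_model()]).
#' @param params A [classifier_params()].
#'
#' @return A one-row data frame: `score`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end` (1-based inclusive; 0 when unaligned),
#'   `n_mismatch`, `n_gap`, `cigar` (with soft clips), plus attribute
#'   `detail` holding the mismatch/gap reference positions.
#' @export
local_align <- function(read_sequence, reference_sequence,
                        params = classifier_params()) {
  if (inherits(reference_sequence, "exon_model"))
    reference_sequence <- reference_sequence$sequence
  aln <- .align_batch_cpp(as.character(read_sequence),
                          as.character(reference_sequence),
                          params$match_score, params$mismatch_penalty,
                          params$gap_open, params$gap_extend)
  out <- data.frame(score = aln$score, ref_start = aln$ref_start,
                    ref_end = aln$ref_end, read_start = aln$read_start,
                    read_end = aln$read_end, n_mismatch = aln$n_mismatch,
                    n_gap = aln$n_ins + aln$n_del, cigar = aln$cigar,
                    stringsAsFactors = FALSE)
  attr(out, "detail") <- list(mismatch_pos = aln$mismatch_pos,
                              del_pos = aln$del_pos, ins_pos = aln$ins_pos)
  out
}

# Align a batch of reads to one reference (both orientations when asked) and
# evaluate the junction rule. Returns one row per read.
.align_evaluate <- function(sequences, ref_seq, junction, window, params) {
  fwd <- .align_batch_cpp(sequences, ref_seq, params$match_score,
                          params$mismatch_penalty, params$gap_open,
                          params$gap_extend)
  strand <- rep("+", length(sequences))
  if (params$both_strands) {
    # a perfect forward alignment cannot be beaten (forward wins ties), so
    # only imperfect reads need the reverse orientation
    retry <- which(fwd$score < params$match_score * nchar(sequences))
    if (length(retry)) {
      rev <- .align_batch_cpp(.revcomp(sequences[retry]), ref_seq,
                              params$match_score, params$mismatch_penalty,
                              params$gap_open, params$gap_extend)
      use_rev <- retry[rev$score > fwd$score[retry]]
      if (length(use_rev)) {
        sel <- match(use_rev, retry)
        for (f in c("score", "ref_start", "ref_end", "read_start", "read_end",
                    "n_mismatch", "n_ins", "n_del", "cigar"))
          fwd[[f]][use_rev] <- rev[[f]][sel]
        for (f in c("mismatch_pos", "del_pos", "ins_pos"))
          fwd[[f]][use_rev] <- rev[[f]][sel]
        strand[use_rev] <- "-"
      }
    }
  }
  .evaluate_junction_rule(fwd, junction, window, params, strand)
}

# Rule evaluation on alignment records already reduced to one per read.
# `aln` is a list of parallel vectors (the .align_batch_cpp layout).
.evaluate_junction_rule <- function(aln, junction, window, params,
                                    strand = NULL) {
  w1 <- window[1L]; w2 <- window[2L]
  rs <- aln$ref_start; re <- aln$ref_end
  aligned <- re >= 1L
  covered <- if (params$overlap_mode == "full_window") {
    rs <= w1 & re >= w2
  } else {
    rs <= w2 & re >= w1
  }
  covered <- covered & aligned

  mm_window <- .count_in_window(aln$mismatch_pos, w1, w2)
  del_window <- .count_in_window(aln$del_pos, w1, w2)
  # an insertion recorded after reference base p lies inside the window when
  # the break p|p+1 is strictly interior to it
  ins_window <- .count_in_window(aln$ins_pos, w1, w2 - 1L)
  gapless <- del_window == 0L & ins_window == 0L

  # aligned reference bases on each side of the junction boundary j|j+1
  del_left <- .count_in_window(aln$del_pos, 1L, junction)
  left_anchor <- pmax(0L, pmin(re, junction) - rs + 1L) - del_left
  del_right <- lengths(aln$del_pos) - del_left
  right_anchor <- pmax(0L, re - pmax(rs - 1L, junction)) - del_right

  satisfies <- covered & gapless &
    left_anchor >= params$min_anchor & right_anchor >= params$min_anchor &
    mm_window <= params$max_mismatch_in_window

  data.frame(score = aln$score, ref_start = rs, ref_end = re,
             read_start = aln$read_start, read_end = aln$read_end,
             n_mismatch = aln$n_mismatch, n_gap = aln$n_ins + aln$n_del,
             mm_window = mm_window, satisfies = satisfies,
             strand = strand %||% rep("+", length(rs)),
             cigar = aln$cigar, stringsAsFactors = FALSE)
}
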