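# Shared fixtures and independent oracles.

# 26-nt three-exon toy transcript used across the suite
fixture_model <- function() {
  exon_model("ACGTACGTACGGGGCCCCTTAATTAA",
             data.frame(exon_label = c("E1", "E2", "E3"),
                        start = c(1, 11, 19), end = c(10, 18, 26)),
             transcript_id = "toy")
}

fixture_pair <- function(window = c(8, 13)) {
  pair <- build_skipped_isoform(fixture_model(), 2)
  set_junction_window(pair, window[1], window[2])
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp_chr <- function(s) {
  vapply(s, function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x),
                                           "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

# Junction k-mer substring oracle: a read is junction evidence for a
# reference iff it (or its reverse complement) contains that reference's
# junction k-mer (min_anchor bases each side) at an offset whose implied
# full-read placement covers the diagnostic window. Exactly one reference
# matching gives the isoform call; both give AMBIGUOUS; none NON_JUNCTION.
oracle_classify <- function(sequences, pair, min_anchor) {
  w1 <- pair$window[1]; w2 <- pair$window[2]
  refs <- list(canonical = pair$junction_pos_canonical,
               skipped = pair$junction_pos_skipped)
  kmer <- lapply(names(refs), function(r) {
    j <- refs[[r]]
    substr(pair[[r]]$sequence, j - min_anchor + 1, j + min_anchor)
  })
  names(kmer) <- names(refs)

  matches_ref <- function(read, r) {
    j <- refs[[r]]
    k <- kmer[[r]]
    for (candidate in c(read, revcomp_chr(read))) {
      hits <- gregexpr(k, candidate, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      for (p in hits) {
        s_impl <- (j - min_anchor + 1) - (p - 1)
        e_impl <- s_impl + nchar(candidate) - 1
        if (s_impl <= w1 && e_impl >= w2) return(TRUE)
      }
    }
    FALSE
  }

  vapply(sequences, function(read) {
    hc <- matches_ref(read, "canonical")
    hs <- matches_ref(read, "skipped")
    if (hc && hs) "AMBIGUOUS"
    else if (hc) "ALPHA"
    else if (hs) "DELTA2"
    else "NON_JUNCTION"
  }, "", USE.NAMES = FALSE)
}

# Independent affine-gap local-alignment score oracle: memoized recursion
# over alignment end states, for tiny strings only.
oracle_local_score <- function(read, ref, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(NA_real_, m + 1, n + 1)
  E <- matrix(NA_real_, m + 1, n + 1)
  F_ <- matrix(NA_real_, m + 1, n + 1)
  NEG <- -1e9
  h <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(H[i + 1, j + 1])) return(H[i + 1, j + 1])
    s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
    v <- max(0, h(i - 1, j - 1) + s, e(i, j), f(i, j))
    H[i + 1, j + 1] <<- v
    v
  }
  e <- function(i, j) {
    if (j == 0) return(NEG)
    if (!is.na(E[i + 1, j + 1])) return(E[i + 1, j + 1])
    v <- max(h(i, j - 1) + gap_open + gap_extend, e(i, j - 1) + gap_extend)
    E[i + 1, j + 1] <<- v
    v
  }
  f <- function(i, j) {
    if (i == 0) return(NEG)
    if (!is.na(F_[i + 1, j + 1])) return(F_[i + 1, j + 1])
    v <- max(h(i - 1, j) + gap_open + gap_extend, f(i - 1, j) + gap_extend)
    F_[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) best <- max(best, h(i, j))
  best
}

# swap the roles of the two isoforms (for the label-symmetry property)
swap_pair <- function(pair) {
  out <- pair
  out$canonical <- pair$skipped
  out$skipped <- pair$canonical
  out$junction_pos_canonical <- pair$junction_pos_skipped
  out$junction_pos_skipped <- pair$junction_pos_canonical
  out
}
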