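test_that("reads spanning one junction get that isoform's call", {
  fx <- fixture_pair()  # window 8-13, junction after base 10
  p3 <- classifier_params(min_anchor = 3)

  expect_equal(classify_read("GTACGGGGCC", fx, p3)$call, "ALPHA")
  expect_equal(classify_read("GTACTTAATT", fx, p3)$call, "DELTA2")
  # shared exon-1 prefix does not cover the window under full_window
  expect_equal(classify_read("ACGTACGT", fx, p3)$call, "NON_JUNCTION")
  # and composition over the same three reads
  cs <- classify_sample(data.frame(read_id = c("r1", "r2", "r3"),
                                   sequence = c("GTACGGGGCC", "GTACTTAATT",
                                                "ACGTACGT")),
                        fx, p3, sample_id = "s")
  expect_equal(cs$counts$n_alpha, 1)
  expect_equal(cs$counts$n_delta2, 1)
  expect_equal(cs$counts$n_nonjunction, 1)
  expect_equal(cs$counts$n_total, 3)

  # reverse-complemented junction reads classify identically
  expect_equal(classify_read(revcomp_chr("GTACGGGGCC"), fx, p3)$call, "ALPHA")
  expect_equal(classify_read(revcomp_chr("GTACTTAATT"), fx, p3)$call, "DELTA2")
})

test_that("equal-scoring window-satisfying reads are AMBIGUOUS, never arbitrary", {
  # pair whose references differ at a single base inside the window (E2/E3
  # share their downstream prefix), so a read carrying a third allele at
  # that base is equidistant from both references
  m <- exon_model(paste0("ACGTACGTAC", "GAGGCCCC", "GTGGCCAA"),
                  data.frame(start = c(1, 11, 19), end = c(10, 18, 26)))
  pair <- set_junction_window(build_skipped_isoform(m, 2), 8, 13)
  p3 <- classifier_params(min_anchor = 3)
  # brute-force search over all single-base variants of the canonical
  # segment spanning bases 5-16: keep those equidistant from both references
  # and window-compatible on both; interior positions only, so the local
  # alignment cannot trim the variant away
  seg <- substr(m$sequence, 5, 16)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  found <- 0
  for (pos in 3:10) for (b in c("A", "C", "G", "T")) {
    read <- seg
    substr(read, pos, pos) <- b
    hc <- ham(read, substr(pair$canonical$sequence, 5, 16))
    hs <- ham(read, substr(pair$skipped$sequence, 5, 16))
    ham_w <- function(ref) ham(substr(read, 4, 9),
                               substr(pair[[ref]]$sequence, 8, 13))
    if (hc == hs && hc == 1 &&
        ham_w("canonical") <= 1 && ham_w("skipped") <= 1) {
      found <- found + 1
      got <- classify_read(read, pair, p3)
      expect_equal(got$call, "AMBIGUOUS", info = read)
      expect_equal(got$margin, 0, info = read)
    }
  }
  expect_gt(found, 0)
})

test_that("empty input yields valid all-zero counts", {
  fx <- fixture_pair()
  cs <- classify_sample(data.frame(read_id = character(),
                                   sequence = character()),
                        fx, classifier_params(min_anchor = 3))
  expect_equal(unlist(cs$counts[, -1]),
               c(n_alpha = 0, n_delta2 = 0, n_ambiguous = 0,
                 n_nonjunction = 0, n_total = 0))
})

test_that("classifier agrees with the junction k-mer substring oracle on error-free reads", {
  for (cfg in list(list(pair = fixture_pair(), rl = 12, anchor = 3),
                   list(pair = synthetic_bax_pair(), rl = 50, anchor = 5))) {
    p <- classifier_params(min_anchor = cfg$anchor)
    sim <- simulate_sample_reads(cfg$pair, 1500, 0.5, read_length = cfg$rl,
                                 seed = 42)
    got <- classify_reads(sim$reads, cfg$pair, p)
    want <- oracle_classify(sim$reads$sequence, cfg$pair, cfg$anchor)
    expect_identical(got$call, want)
  }
})

test_that("swapping the isoform labels swaps the class counts exactly", {
  pair <- synthetic_bax_pair()
  sim <- simulate_sample_reads(pair, 1000, 0.3, read_length = 50, seed = 9,
                               substitution_rate = 0.01)
  a <- classify_sample(sim$reads, pair, sample_id = "s")$counts
  b <- classify_sample(sim$reads, swap_pair(pair), sample_id = "s")$counts
  expect_equal(a$n_alpha, b$n_delta2)
  expect_equal(a$n_delta2, b$n_alpha)
  expect_equal(a$n_ambiguous, b$n_ambiguous)
  expect_equal(a$n_nonjunction, b$n_nonjunction)
})

test_that("stricter thresholds never gain junction reads; counts always conserve", {
  pair <- synthetic_bax_pair()
  sim <- simulate_sample_reads(pair, 800, 0.4, read_length = 50, seed = 13,
                               substitution_rate = 0.02)
  junction_reads <- function(anchor, max_mm) {
    cnt <- classify_sample(sim$reads, pair,
                           classifier_params(min_anchor = anchor,
                                             max_mismatch_in_window = max_mm),
                           sample_id = "s")$counts
    expect_equal(cnt$n_alpha + cnt$n_delta2 + cnt$n_ambiguous +
                   cnt$n_nonjunction, cnt$n_total)
    expect_equal(cnt$n_total, nrow(sim$reads))
    cnt$n_alpha + cnt$n_delta2
  }
  j_anchor <- vapply(c(3, 5, 8, 12), junction_reads, numeric(1), max_mm = 2)
  expect_true(all(diff(j_anchor) <= 0))
  j_mm <- vapply(c(3, 1, 0), junction_reads, numeric(1), anchor = 5)
  expect_true(all(diff(j_mm) <= 0))
})

test_that("any_overlap mode admits reads that touch but do not cover the window", {
  fx <- fixture_pair()  # window 8-13
  # read over bases 6-13 covers only part of a 8-14 window placement
  pair14 <- set_junction_window(fx, 8, 14)
  read <- substr(pair14$canonical$sequence, 6, 13)
  p_full <- classifier_params(min_anchor = 3, overlap_mode = "full_window")
  p_any <- classifier_params(min_anchor = 3, overlap_mode = "any_overlap")
  expect_equal(classify_read(read, pair14, p_full)$call, "NON_JUNCTION")
  expect_equal(classify_read(read, pair14, p_any)$call, "ALPHA")
})

test_that("paired mates merge to one fragment-level call", {
  fx <- fixture_pair()
  p3 <- classifier_params(min_anchor = 3)
  reads <- data.frame(
    read_id = c("f1/1", "f1/2", "f2/1", "f2/2", "f3/1", "f3/2"),
    sequence = c("GTACGGGGCC", "ACGTACGT",    # ALPHA + NON_JUNCTION
                 "GTACGGGGCC", "GTACTTAATT",  # conflicting mates
                 "ACGTACGT", "ACGTACGT"))     # neither informative
  cs <- classify_sample(reads, fx, p3, sample_id = "s")
  expect_equal(cs$counts$n_total, 3)
  calls <- setNames(cs$calls$call, cs$calls$read_id)
  expect_equal(unname(calls["f1"]), "ALPHA")
  expect_equal(unname(calls["f2"]), "AMBIGUOUS")
  expect_equal(unname(calls["f3"]), "NON_JUNCTION")
})
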