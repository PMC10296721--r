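test_that("exon models validate tiling, case and alphabet", {
  m <- fixture_model()
  expect_s3_class(m, "exon_model")
  expect_equal(nrow(m$exons), 3)
  expect_equal(nchar(m$sequence), 26)
  expect_equal(unname(exon_lengths(m)), c(10, 8, 8))

  # a 1-base gap between exons is rejected, naming the offending base
  expect_error(
    exon_model("ACGTACGTACGGGGCCCCTTAATTAA",
               data.frame(start = c(1, 12, 19), end = c(10, 18, 26))),
    "gap at base 11")
  expect_error(
    exon_model("ACGTACGTACGGGGCCCCTTAATTAA",
               data.frame(start = c(1, 10, 19), end = c(10, 18, 26))),
    "overlap at base 10")
  expect_error(
    exon_model("ACGTACGTACGGGGCCCCTTAATTAA",
               data.frame(start = c(1, 11), end = c(10, 18))),
    "gap at base 19")

  # lowercase and U are normalized; empty and dirty sequences are errors
  lower <- exon_model(tolower("ACGTACGTACGGGGCCCCTTAATTAA"),
                      m$exons, transcript_id = "toy")
  expect_identical(lower$sequence, m$sequence)
  rna <- exon_model("acgu", data.frame(start = 1, end = 4))
  expect_identical(rna$sequence, "ACGT")
  expect_error(exon_model("", data.frame(start = 1, end = 1)), "empty")
  expect_error(exon_model("ACGX", data.frame(start = 1, end = 4)),
               "outside")
})

test_that("references load from FASTA plus an exon-interval TSV", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy some description", "ACGTACGTACGGGG", "CCCCTTAATTAA"), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("exon_label\tstart_1based\tend_1based",
               "E1\t1\t10", "E2\t11\t18", "E3\t19\t26"), tsv)
  m <- load_reference(fa, tsv)
  expect_identical(m$sequence, fixture_model()$sequence)
  expect_identical(m$transcript_id, "toy")
  expect_identical(m$exons$exon_label, c("E1", "E2", "E3"))

  # multi-record files need an explicit record name
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTACGTACGGGGCCCCTTAATTAA"), fa2)
  expect_error(load_reference(fa2, tsv), "2 records")
  m2 <- load_reference(fa2, tsv, record = "b")
  expect_identical(m2$sequence, m$sequence)
  expect_error(load_reference(fa2, tsv, record = "zz"), "not found")
})

test_that("skipped isoform is the canonical sequence minus the skipped exon", {
  m <- fixture_model()
  pair <- build_skipped_isoform(m, 2)
  expect_identical(pair$skipped$sequence, "ACGTACGTACTTAATTAA")
  expect_equal(nchar(pair$skipped$sequence), 18)
  expect_equal(pair$junction_pos_canonical, 10)
  expect_equal(pair$junction_pos_skipped, 10)
  expect_identical(pair$skipped$exons$exon_label, c("E1", "E3"))

  # terminal exon skips and label addressing
  first <- build_skipped_isoform(m, 1)
  expect_identical(first$skipped$sequence, "GGGGCCCCTTAATTAA")
  by_label <- build_skipped_isoform(m, "E2")
  expect_identical(by_label$skipped$sequence, pair$skipped$sequence)

  expect_error(build_skipped_isoform(m, 7), "out of range")
  expect_error(build_skipped_isoform(m, "E9"), "no exon labelled")

  # supplied skipped sequence is validated against the derived one
  expect_silent(build_skipped_isoform(m, 2,
                                      skipped_sequence = "ACGTACGTACTTAATTAA"))
  expect_error(build_skipped_isoform(m, 2,
                                     skipped_sequence = "ACGTACGTACTTAATTAG"),
               "differs")
})

test_that("round trip and length conservation hold for random exon models", {
  set.seed(42)
  for (rep in 1:20) {
    n_ex <- sample(2:6, 1)
    lens <- sample(4:30, n_ex, replace = TRUE)
    seqs <- vapply(lens, rand_seq, "")
    ends <- cumsum(lens)
    m <- exon_model(paste(seqs, collapse = ""),
                    data.frame(start = c(1, head(ends, -1) + 1), end = ends))
    k <- sample(n_ex, 1)
    pair <- build_skipped_isoform(m, k)
    # length conservation
    expect_equal(nchar(m$sequence) - nchar(pair$skipped$sequence), lens[k])
    # re-inserting the skipped exon's bases reproduces the canonical sequence
    at <- m$exons$start[k]
    rebuilt <- paste0(substr(pair$skipped$sequence, 1, at - 1),
                      seqs[k],
                      substr(pair$skipped$sequence, at,
                             nchar(pair$skipped$sequence)))
    expect_identical(rebuilt, m$sequence)
  }
})

test_that("coordinate rendering round-trips through 1-based inclusive text", {
  m <- fixture_model()
  rendered <- sprintf("%s\t%d\t%d", m$exons$exon_label, m$exons$start,
                      m$exons$end)
  reparsed <- utils::read.delim(text = paste(rendered, collapse = "\n"),
                                header = FALSE,
                                col.names = c("exon_label", "start", "end"))
  m2 <- exon_model(m$sequence, reparsed)
  expect_identical(m2$exons$start, m$exons$start)
  expect_identical(m2$exons$end, m$exons$end)
})

test_that("junction window defaults to bases 30-40 and must span the junction", {
  bax <- synthetic_bax_pair()
  pair <- build_skipped_isoform(
    exon_model(bax$canonical$sequence, bax$canonical$exons), 2)
  expect_null(pair$window)
  pair <- set_junction_window(pair)  # default
  expect_equal(pair$window, c(30L, 40L))

  fx <- build_skipped_isoform(fixture_model(), 2)
  expect_equal(set_junction_window(fx, 8, 13)$window, c(8L, 13L))
  expect_error(set_junction_window(fx, 1, 5), "does not span the junction")
  expect_error(set_junction_window(fx, 12, 14), "does not span the junction")
  expect_error(set_junction_window(fx, 5, 30), "exceeds")
  expect_error(set_junction_window(fx, 9, 8), "start <= end")
})

test_that("the synthetic BAX-like pair has the documented junction geometry", {
  pair <- synthetic_bax_pair()
  expect_equal(pair$junction_pos_canonical, 35)
  expect_equal(nchar(pair$canonical$sequence), 240)
  expect_equal(nchar(pair$skipped$sequence), 192)
  # the two 10-base junction k-mers differ at all five bases past the junction
  kc <- substr(pair$canonical$sequence, 31, 40)
  ks <- substr(pair$skipped$sequence, 31, 40)
  expect_identical(substr(kc, 1, 5), substr(ks, 1, 5))
  expect_equal(sum(strsplit(substr(kc, 6, 10), "")[[1]] ==
                     strsplit(substr(ks, 6, 10), "")[[1]]), 0)
  # each k-mer occurs exactly once, on its own reference only
  count_hits <- function(p, s) {
    g <- gregexpr(p, s, fixed = TRUE)[[1]]
    length(g[g > 0])
  }
  expect_equal(count_hits(kc, pair$canonical$sequence), 1)
  expect_equal(count_hits(kc, pair$skipped$sequence), 0)
  expect_equal(count_hits(ks, pair$skipped$sequence), 1)
  expect_equal(count_hits(ks, pair$canonical$sequence), 0)
})
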