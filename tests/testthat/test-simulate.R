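test_that("degenerate mixture fractions give all-or-nothing truth tables", {
  pair <- fixture_pair()
  none <- simulate_sample_reads(pair, 100, 0, read_length = 12, seed = 1)
  expect_equal(sum(none$truth$source_isoform == "skipped"), 0)
  all_ <- simulate_sample_reads(pair, 100, 1, read_length = 12, seed = 1)
  expect_equal(sum(all_$truth$source_isoform == "skipped"), 100)
  expect_equal(nrow(all_$reads), 100)

  empty <- simulate_sample_reads(pair, 0, 0.5, read_length = 12)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)

  expect_error(simulate_sample_reads(pair, 10, 0.5, read_length = 19),
               "exceeds")
})

test_that("skipped-read counts follow the binomial sampling model", {
  pair <- fixture_pair()
  sim <- simulate_sample_reads(pair, 10000, 0.3, read_length = 12, seed = 7)
  k <- sum(sim$truth$source_isoform == "skipped")
  # binomial oracle: mean 3000, sd sqrt(10000 * .3 * .7) = 45.83
  expect_gt(k, 3000 - 3 * 45.83)
  expect_lt(k, 3000 + 3 * 45.83)
})

test_that("error-free reads are exact substrings of their source at source_start", {
  pair <- synthetic_bax_pair()
  sim <- simulate_sample_reads(pair, 500, 0.4, read_length = 50, seed = 11)
  src <- ifelse(sim$truth$source_isoform == "skipped",
                pair$skipped$sequence, pair$canonical$sequence)
  expected <- substr(src, sim$truth$source_start,
                     sim$truth$source_start + 49)
  expect_identical(sim$reads$sequence, expected)
  expect_true(all(sim$truth$n_substitutions == 0))
  # spans_window is consistent with start, read length and the window
  spans <- sim$truth$source_start <= pair$window[1] &
    sim$truth$source_start + 49 >= pair$window[2]
  expect_identical(sim$truth$spans_window, spans)
})

test_that("substituted reads differ from the source at the stated rate", {
  pair <- synthetic_bax_pair()
  n <- 20000
  rate <- 0.01
  sim <- simulate_sample_reads(pair, n, 0.5, read_length = 50,
                               substitution_rate = rate, seed = 5)
  src <- ifelse(sim$truth$source_isoform == "skipped",
                pair$skipped$sequence, pair$canonical$sequence)
  raw <- substr(src, sim$truth$source_start, sim$truth$source_start + 49)
  ham <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                sim$reads$sequence, raw, USE.NAMES = FALSE)
  expect_identical(unname(ham), sim$truth$n_substitutions)
  # mean substitutions per read ~ Binomial(read_length, rate) mean, 3 sd band
  total <- sum(ham)
  expect_gt(total, n * 50 * rate - 3 * sqrt(n * 50 * rate * (1 - rate)))
  expect_lt(total, n * 50 * rate + 3 * sqrt(n * 50 * rate * (1 - rate)))
})

test_that("identical seeds give byte-identical FASTQ and truth outputs", {
  pair <- synthetic_bax_pair()
  design <- cohort_design(n_per_group = c(AD = 3L, NCI = 3L), n_reads = 50L)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  c1 <- simulate_cohort(pair, design, d1, seed = 99)
  c2 <- simulate_cohort(pair, design, d2, seed = 99)
  for (s in names(c1$fastq_paths))
    expect_identical(readBin(c1$fastq_paths[[s]], "raw", 1e6),
                     readBin(c2$fastq_paths[[s]], "raw", 1e6))
  expect_identical(readLines(c1$truth_path), readLines(c2$truth_path))
  expect_identical(readLines(c1$metadata_path), readLines(c2$metadata_path))
  # a different seed changes the reads
  c3 <- simulate_cohort(pair, design, file.path(tempfile(), "c"), seed = 100)
  expect_false(identical(readLines(c1$fastq_paths[[1]]),
                         readLines(c3$fastq_paths[[1]])))
})

test_that("cohort metadata and truth tables have the designed structure", {
  pair <- synthetic_bax_pair()
  design <- cohort_design(n_per_group = c(AD = 4L, NCI = 4L),
                          zero_inflation = c(AD = 1, NCI = 0),
                          beta_shape1 = c(AD = 2, NCI = 2),
                          beta_shape2 = c(AD = 2, NCI = 2),
                          n_reads = 10L)
  cc <- simulate_cohort(pair, design, tempfile(), seed = 3)
  expect_equal(nrow(cc$metadata), 8)
  expect_identical(colnames(cc$metadata),
                   c("sample_id", "group", "sex", "apoe", "age"))
  # all-zero inflation in AD: exactly the 4 AD rows have true_fraction 0
  expect_equal(sum(cc$truth$true_fraction == 0), 4)
  expect_true(all(cc$truth$group[cc$truth$true_fraction == 0] == "AD"))
  expect_true(all(file.exists(cc$fastq_paths)))
  expect_true(all(cc$metadata$sex %in% c("F", "M")))
  expect_true(all(cc$metadata$apoe %in% c("22", "23", "24", "33", "34", "44")))
  expect_true(all(cc$metadata$age >= 70 & cc$metadata$age <= 104))

  # an empty group is allowed and the metadata stays valid
  lone <- cohort_design(n_per_group = c(AD = 2L, NCI = 0L), n_reads = 5L)
  cl <- simulate_cohort(pair, lone, tempfile(), seed = 4)
  expect_equal(nrow(cl$metadata), 2)
  expect_true(all(cl$metadata$group == "AD"))
})

test_that("paired mode emits mate pairs with consistent truth", {
  pair <- synthetic_bax_pair()
  sim <- simulate_sample_reads(pair, 50, 0.5, read_length = 40, seed = 2,
                               paired = TRUE)
  expect_equal(nrow(sim$reads), 100)
  expect_true(all(grepl("/[12]$", sim$reads$read_id)))
  # mate 2 is the reverse complement of a source window: check via truth
  m2 <- sim$reads$read_id[seq(2, 100, 2)]
  t2 <- sim$truth[match(m2, sim$truth$read_id), ]
  src <- ifelse(t2$source_isoform == "skipped", pair$skipped$sequence,
                pair$canonical$sequence)
  fwd <- substr(src, t2$source_start, t2$source_start + 39)
  expect_identical(sim$reads$sequence[seq(2, 100, 2)], revcomp_chr(fwd))
})

test_that("cohort design validates its probability inputs", {
  expect_error(cohort_design(n_per_group = c(3L, 3L)), "unique group names")
  expect_error(cohort_design(zero_inflation = c(AD = 0.5)), "named for every group")
  expect_error(cohort_design(apoe_freq = c(`33` = 0.5, `34` = 0.4)),
               "sum to 1")
  expect_error(cohort_design(sex_freq = list(AD = c(F = 0.9, M = 0.2),
                                             NCI = c(F = 0.5, M = 0.5))),
               "sum to 1")
})
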