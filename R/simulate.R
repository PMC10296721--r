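#' Cohort design for the read simulator
#'
#' Describes the synthetic case-control cohort the simulator generates: group
#' sizes, the per-group distribution of the true skipping fraction, and the
#' clinical-metadata generators. The skipping fraction follows a zero-inflated
#' Beta: with probability `zero_inflation[g]` a sample carries no skipped
#' transcripts at all, otherwise its fraction is drawn from
#' `Beta(beta_shape1[g], beta_shape2[g])`. The defaults emulate the published
#' frontal-lobe cohort: 324 AD / 327 NCI samples, expected skipping prevalence
#' 85% in AD and 48% in NCI, group-specific sex frequencies, and pooled APOE
#' genotype frequencies.
#'
#' @param n_per_group Named integer vector of samples per diagnosis group.
#' @param zero_inflation Named probability, per group, that a sample's true
#'   skipping fraction is exactly zero (prevalence is its complement).
#' @param beta_shape1,beta_shape2 Named Beta shape parameters, per group, of
#'   the non-zero skipping fraction.
#' @param sex_freq Named list (per group) of named probabilities over
#'   `{"F","M"}`.
#' @param apoe_freq Named probabilities over APOE genotypes.
#' @param age_mean,age_sd,age_range Normal age model, truncated to
#'   `age_range` and rounded to whole years.
#' @param n_reads,read_length,substitution_rate Per-sample read simulation
#'   settings passed to [simulate_sample_reads()].
#'
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = c(AD = 324L, NCI = 327L),
                          zero_inflation = c(AD = 0.15, NCI = 0.52),
                          beta_shape1 = c(AD = 2, NCI = 1.5),
                          beta_shape2 = c(AD = 8, NCI = 12),
                          sex_freq = list(AD = c(F = 210, M = 78) / 288,
                                          NCI = c(F = 209, M = 117) / 326),
                          apoe_freq = c(`22` = 5, `23` = 96, `24` = 16,
                                        `33` = 515, `34` = 171, `44` = 12) / 815,
                          age_mean = 85, age_sd = 6, age_range = c(70, 104),
                          n_reads = 600L, read_length = 50L,
                          substitution_rate = 0.005) {
  groups <- names(n_per_group)
  if (is.null(groups) || anyDuplicated(groups))
    stop("input error: n_per_group must carry unique group names",
         call. = FALSE)
  for (nm in c("zero_inflation", "beta_shape1", "beta_shape2")) {
    v <- get(nm)
    if (!all(groups %in% names(v)))
      stop(sprintf("input error: %s must be named for every group", nm),
           call. = FALSE)
  }
  stopifnot(all(zero_inflation >= 0 & zero_inflation <= 1),
            all(beta_shape1 > 0), all(beta_shape2 > 0))
  for (g in groups) {
    p <- sex_freq[[g]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("input error: sex_freq[['%s']] must sum to 1", g),
           call. = FALSE)
  }
  if (abs(sum(apoe_freq) - 1) > 1e-8)
    stop("input error: apoe_freq must sum to 1", call. = FALSE)
  structure(list(n_per_group = n_per_group, zero_inflation = zero_inflation,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 sex_freq = sex_freq, apoe_freq = apoe_freq,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate),
            class = "cohort_design")
}

#' Simulate reads for one sample from a two-isoform mixture
#'
#' Draws `n_reads` single-end reads from the pair of references: each read's
#' source isoform is Bernoulli(`fraction_skipped`), its start position is
#' uniform over all positions where the read fits on the source transcript,
#' and independent substitutions are applied at `substitution_rate` per base
#' (each substitution replaces the base with one of the three other bases,
#' uniformly). Quality strings are constant `"I"`. Read ids carry no
#' information about the source isoform; the truth is returned separately.
#'
#' @param pair An [build_skipped_isoform()] result (window set if
#'   `spans_window` truth flags are wanted).
#' @param n_reads Number of reads (fragments when `paired = TRUE`).
#' @param fraction_skipped True proportion of transcript molecules that are
#'   the skipped isoform, in `[0, 1]`.
#' @param read_length Read length in bases.
#' @param substitution_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional integer seed (`set.seed`); when `NULL` the current RNG
#'   stream is used.
#' @param paired Generate mate pairs (`/1` forward, `/2` reverse-complemented
#'   from the other end of a fragment twice the read length, capped at the
#'   transcript). Default single-end.
#' @param id_prefix Prefix for read ids.
#'
#' @return A list with `reads` (data frame `read_id`, `sequence`, `quality`)
#'   and `truth` (data frame `read_id`, `source_isoform`, `source_start`
#'   (1-based on the source transcript), `n_substitutions`, `spans_window`).
#' @export
simulate_sample_reads <- function(pair, n_reads, fraction_skipped,
                                  read_length = 50L, substitution_rate = 0,
                                  seed = NULL, paired = FALSE,
                                  id_prefix = "read") {
  stopifnot(inherits(pair, "isoform_pair"))
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  stopifnot(n_reads >= 0L, read_length >= 2L,
            fraction_skipped >= 0, fraction_skipped <= 1,
            substitution_rate >= 0, substitution_rate < 1)
  if (!is.null(seed)) set.seed(seed)

  seq_c <- pair$canonical$sequence
  seq_s <- pair$skipped$sequence
  len_min <- min(nchar(seq_c), nchar(seq_s))
  if (read_length > len_min)
    stop(sprintf("input error: read_length %d exceeds the %d-base shorter transcript",
                 read_length, len_min), call. = FALSE)

  empty <- list(
    reads = data.frame(read_id = character(), sequence = character(),
                       quality = character(), stringsAsFactors = FALSE),
    truth = data.frame(read_id = character(), source_isoform = character(),
                       source_start = integer(), n_substitutions = integer(),
                       spans_window = logical(), stringsAsFactors = FALSE))
  if (n_reads == 0L) return(empty)

  from_skipped <- stats::runif(n_reads) < fraction_skipped
  src_seq <- ifelse(from_skipped, seq_s, seq_c)
  src_len <- ifelse(from_skipped, nchar(seq_s), nchar(seq_c))

  if (!paired) {
    start <- 1L + as.integer(floor(stats::runif(n_reads) *
                                     (src_len - read_length + 1L)))
    raw <- substring(src_seq, start, start + read_length - 1L)
    mut <- .apply_substitutions(raw, substitution_rate)
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n_reads))
    reads <- data.frame(read_id = ids, sequence = mut$sequence,
                        quality = strrep("I", read_length),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids,
                        source_isoform = ifelse(from_skipped, "skipped",
                                                "canonical"),
                        source_start = start,
                        n_substitutions = mut$n_substitutions,
                        spans_window = .spans_window(pair, start, read_length),
                        stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }

  # paired: fragment of length min(2 * read_length, transcript length)
  frag_len <- pmin(2L * read_length, src_len)
  fstart <- 1L + as.integer(floor(stats::runif(n_reads) *
                                    (src_len - frag_len + 1L)))
  s1 <- fstart
  s2 <- fstart + frag_len - read_length
  raw1 <- substring(src_seq, s1, s1 + read_length - 1L)
  raw2 <- substring(src_seq, s2, s2 + read_length - 1L)
  mut1 <- .apply_substitutions(raw1, substitution_rate)
  mut2 <- .apply_substitutions(raw2, substitution_rate)
  base <- sprintf("%s_%06d", id_prefix, seq_len(n_reads))
  ids <- c(rbind(paste0(base, "/1"), paste0(base, "/2")))
  seqs <- c(rbind(mut1$sequence, .revcomp(mut2$sequence)))
  reads <- data.frame(read_id = ids, sequence = seqs,
                      quality = strrep("I", read_length),
                      stringsAsFactors = FALSE)
  iso <- ifelse(from_skipped, "skipped", "canonical")
  truth <- data.frame(read_id = ids,
                      source_isoform = rep(iso, each = 2L),
                      source_start = c(rbind(s1, s2)),
                      n_substitutions = c(rbind(mut1$n_substitutions,
                                                mut2$n_substitutions)),
                      spans_window = c(rbind(
                        .spans_window(pair, s1, read_length),
                        .spans_window(pair, s2, read_length))),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

.apply_substitutions <- function(sequences, rate) {
  n_sub <- integer(length(sequences))
  if (rate > 0 && length(sequences)) {
    rl <- nchar(sequences)
    n_sub <- stats::rbinom(length(sequences), rl, rate)
    for (i in which(n_sub > 0L)) {
      pos <- sample.int(rl[i], n_sub[i])
      for (p in pos) {
        old <- substr(sequences[i], p, p)
        alt <- setdiff(c("A", "C", "G", "T"), old)
        substr(sequences[i], p, p) <- sample(alt, 1L)
      }
    }
  }
  list(sequence = sequences, n_substitutions = n_sub)
}

.spans_window <- function(pair, start, read_length) {
  if (is.null(pair$window)) return(rep(NA, length(start)))
  start <= pair$window[1L] & (start + read_length - 1L) >= pair$window[2L]
}

#' Write reads to a FASTQ file
#'
#' Plain four-line records, Unix newlines, written bytewise so identical
#' inputs give byte-identical files.
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(c(rbind(paste0("@", reads$read_id), reads$sequence, "+",
                       reads$quality)), con, sep = "\n")
  invisible(path)
}

#' Simulate a whole mock cohort
#'
#' Draws per-sample true skipping fractions and clinical metadata from a
#' [cohort_design()], simulates one FASTQ per sample against the isoform
#' pair, and writes a metadata table and a truth table. All randomness flows
#' from `seed`, so a rerun with the same arguments is byte-identical.
#'
#' @param pair An isoform pair with its junction window set.
#' @param design A [cohort_design()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#'
#' @return A list with `metadata` and `truth` data frames, the vector of
#'   FASTQ `fastq_paths`, and the paths of the two TSV files.
#' @export
simulate_cohort <- function(pair, design, out_dir, seed = 1L) {
  stopifnot(inherits(pair, "isoform_pair"), inherits(design, "cohort_design"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", out_dir, call. = FALSE)
  set.seed(seed)

  meta <- .draw_cohort_samples(design)
  fastq_paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sim <- simulate_sample_reads(pair, design$n_reads,
                                 meta$true_fraction[i],
                                 read_length = design$read_length,
                                 substitution_rate = design$substitution_rate,
                                 id_prefix = meta$sample_id[i])
    fastq_paths[i] <- file.path(out_dir, paste0(meta$sample_id[i], ".fastq"))
    write_fastq(sim$reads, fastq_paths[i])
  }
  names(fastq_paths) <- meta$sample_id

  metadata <- meta[, c("sample_id", "group", "sex", "apoe", "age")]
  truth <- meta[, c("sample_id", "group", "true_fraction")]
  metadata_path <- file.path(out_dir, "metadata.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  .write_tsv(metadata, metadata_path,
             provenance = sprintf("simulate_cohort seed=%d n_reads=%d read_length=%d substitution_rate=%g",
                                  seed, design$n_reads, design$read_length,
                                  design$substitution_rate))
  .write_tsv(truth, truth_path,
             provenance = sprintf("simulate_cohort truth seed=%d", seed))
  list(metadata = metadata, truth = truth, fastq_paths = fastq_paths,
       metadata_path = metadata_path, truth_path = truth_path)
}

# shared sample-level draws (fractions + metadata), using the current RNG
.draw_cohort_samples <- function(design) {
  out <- list()
  for (g in names(design$n_per_group)) {
    n <- design$n_per_group[[g]]
    if (n == 0L) next
    zero <- stats::runif(n) < design$zero_inflation[[g]]
    frac <- ifelse(zero, 0,
                   stats::rbeta(n, design$beta_shape1[[g]],
                                design$beta_shape2[[g]]))
    sexp <- design$sex_freq[[g]]
    age <- round(stats::qnorm(
      stats::runif(n,
                   stats::pnorm(design$age_range[1L], design$age_mean, design$age_sd),
                   stats::pnorm(design$age_range[2L], design$age_mean, design$age_sd)),
      design$age_mean, design$age_sd))
    out[[g]] <- data.frame(
      sample_id = sprintf("SAMPLE_%s_%03d", g, seq_len(n)),
      group = g,
      sex = sample(names(sexp), n, replace = TRUE, prob = sexp),
      apoe = sample(names(design$apoe_freq), n, replace = TRUE,
                    prob = design$apoe_freq),
      age = as.integer(age),
      true_fraction = frac,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(), group = character(),
                      sex = character(), apoe = character(), age = integer(),
                      true_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a cohort at the junction-read-count level
#'
#' The fast counterpart of [simulate_cohort()] for statistical studies that
#' do not need base-level reads: per sample it draws the true skipping
#' fraction and metadata exactly as [simulate_cohort()] does, then draws the
#' junction-read depth `n ~ Poisson(mean_junction_reads)` and the
#' skip-junction count `n_delta2 ~ Binomial(n, fraction)` directly, which is
#' the generative model an unbiased junction classifier samples from.
#'
#' @param design A [cohort_design()].
#' @param mean_junction_reads Mean junction-read depth per sample.
#' @param seed Optional integer seed.
#'
#' @return A data frame with metadata columns plus `true_fraction`,
#'   `n_alpha`, `n_delta2`, `n_ambiguous`, `n_nonjunction`, `n_total`.
#' @export
simulate_counts_cohort <- function(design, mean_junction_reads = 100,
                                   seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  meta <- .draw_cohort_samples(design)
  n <- stats::rpois(nrow(meta), mean_junction_reads)
  nd <- stats::rbinom(nrow(meta), n, meta$true_fraction)
  meta$n_alpha <- n - nd
  meta$n_delta2 <- nd
  meta$n_ambiguous <- 0L
  meta$n_nonjunction <- 0L
  meta$n_total <- n
  meta
}
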