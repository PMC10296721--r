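#' Join per-sample quantification to clinical metadata
#'
#' Inner join on `sample_id`, mirroring the link-and-match step between
#' RNA-seq datasets and clinical/biospecimen tables. Unmatched rows on
#' either side are reported via the `unmatched` attribute (and a message).
#'
#' @param quant_rows Data frame of quantified samples (must carry
#'   `sample_id`).
#' @param metadata Data frame of clinical metadata with a `sample_id` key
#'   column, or the path of a metadata TSV.
#'
#' @return The joined data frame, with attribute `unmatched` (a list with
#'   `quant` and `metadata` id vectors).
#' @export
link_metadata <- function(quant_rows, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- .read_tsv(metadata)
  stopifnot(is.data.frame(quant_rows), is.data.frame(metadata))
  if (!"sample_id" %in% colnames(quant_rows))
    stop("input error: quantification rows lack a sample_id column",
         call. = FALSE)
  if (!"sample_id" %in% colnames(metadata))
    stop("input error: metadata lacks a sample_id key column", call. = FALSE)
  joined <- merge(quant_rows, metadata, by = "sample_id", sort = TRUE)
  unmatched <- list(
    quant = setdiff(quant_rows$sample_id, metadata$sample_id),
    metadata = setdiff(metadata$sample_id, quant_rows$sample_id))
  if (length(unmatched$quant) || length(unmatched$metadata))
    message(sprintf("link_metadata: %d quantified sample(s) and %d metadata row(s) unmatched",
                    length(unmatched$quant), length(unmatched$metadata)))
  attr(joined, "unmatched") <- unmatched
  joined
}

#' Run the full quantification pipeline over a sample manifest
#'
#' For every manifest row the reads are classified against the isoform pair,
#' junction-read tallies are converted to the skipped-isoform percentage,
#' results are joined to the metadata, de-identified, and summarized;
#' finally the case-control statistics are computed when both contrast
#' groups reach the minimum size.
#'
#' @param manifest Data frame with `sample_id` and `reads_path` columns
#'   (FASTQ or SAM/BAM per sample), plus optional metadata columns
#'   (`group`, `sex`, `apoe`, `age`) -- or the path of a manifest TSV.
#' @param pair Isoform pair with junction window set.
#' @param params [classifier_params()].
#' @param metadata Optional separate metadata table or TSV path (joined on
#'   `sample_id`); metadata columns already present in the manifest are used
#'   directly when this is `NULL`.
#' @param out_dir Output directory for the summary and stats TSVs (`NULL`
#'   for none).
#' @param min_skip_reads Presence threshold for [flag_splicing()].
#' @param groups Contrast passed to [cohort_stats()].
#' @param min_group_size Minimum samples per contrast group for statistics
#'   (default 3); below it the stats step is skipped with a reason.
#' @param seed Seed for the de-identification shuffle.
#' @param id_map_path Optional path for the de-identification map.
#' @param keep_going Continue past per-sample failures (failed samples are
#'   dropped with a warning) instead of stopping.
#'
#' @return A list with `table` (de-identified cohort table), `counts`
#'   (raw per-sample tallies, original ids), `stats` (a comparison frame or
#'   `NULL`), `stats_note`, and the output paths written.
#' @export
run_pipeline <- function(manifest, pair, params = classifier_params(),
                         metadata = NULL, out_dir = NULL,
                         min_skip_reads = 1L, groups = c("AD", "NCI"),
                         min_group_size = 3L, seed = 1L,
                         id_map_path = NULL, keep_going = FALSE) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- .read_tsv(manifest)
  stopifnot(is.data.frame(manifest),
            all(c("sample_id", "reads_path") %in% colnames(manifest)))
  if (anyDuplicated(manifest$sample_id))
    stop(sprintf("input error: duplicate sample_id in manifest: %s",
                 paste(unique(manifest$sample_id[duplicated(manifest$sample_id)]),
                       collapse = ", ")), call. = FALSE)

  counts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      classify_sample(manifest$reads_path[i], pair, params,
                      sample_id = manifest$sample_id[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (!keep_going)
        stop(sprintf("sample '%s' failed: %s", manifest$sample_id[i],
                     conditionMessage(res)), call. = FALSE)
      warning(sprintf("sample '%s' failed and was dropped: %s",
                      manifest$sample_id[i], conditionMessage(res)),
              call. = FALSE)
      next
    }
    counts[[i]] <- res$counts
  }
  counts <- do.call(rbind, counts[!vapply(counts, is.null, logical(1))])
  quant <- compute_ratio(counts, min_skip_reads = min_skip_reads)

  meta_cols <- intersect(c("group", "sex", "apoe", "age"), colnames(manifest))
  if (!is.null(metadata)) {
    quant <- link_metadata(quant, metadata)
  } else if (length(meta_cols)) {
    quant <- merge(quant, manifest[, c("sample_id", meta_cols), drop = FALSE],
                   by = "sample_id", sort = TRUE)
  }

  table <- deidentify(quant, seed = seed, id_map_path = id_map_path)

  stats <- NULL
  stats_note <- NULL
  have_groups <- "group" %in% colnames(table)
  if (have_groups) {
    sizes <- vapply(groups, function(g) sum(table$group == g), numeric(1))
    if (all(sizes >= min_group_size)) {
      stats <- cohort_stats(table, groups = groups)
    } else {
      stats_note <- sprintf("statistics skipped: group sizes (%s) below minimum %d",
                            paste(sprintf("%s=%d", groups, sizes),
                                  collapse = ", "), min_group_size)
      message(stats_note)
    }
  } else {
    stats_note <- "statistics skipped: no group column"
  }

  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)
    prov <- c(sprintf("baxsplice %s",
                      as.character(utils::packageVersion("baxsplice"))),
              sprintf("window=%d-%d min_anchor=%d max_mismatch_in_window=%d overlap_mode=%s",
                      pair$window[1L], pair$window[2L], params$min_anchor,
                      params$max_mismatch_in_window, params$overlap_mode),
              sprintf("min_skip_reads=%d seed=%d", min_skip_reads, seed))
    paths$summary <- file.path(out_dir, "cohort_summary.tsv")
    write_summary(table, paths$summary, provenance = prov)
    if (!is.null(stats)) {
      paths$stats <- file.path(out_dir, "group_stats.tsv")
      write_stats_report(stats, paths$stats, provenance = prov)
    }
  }

  list(table = table, counts = counts, stats = stats,
       stats_note = stats_note, paths = paths)
}
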