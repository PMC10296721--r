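#' Prevalence of exon skipping within a diagnosis group
#'
#' Percentage of samples in the group flagged as containing skip-junction
#' evidence. Samples with an `NA` skipping percentage (no junction reads)
#' count in the denominator -- absence of evidence is counted as absence for
#' prevalence.
#'
#' @param table Cohort table with `group` and `has_splicing` columns.
#' @param group Group label.
#' @param group_col Name of the group column.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) for an empty
#'   group.
#' @export
prevalence <- function(table, group, group_col = "group") {
  stopifnot(is.data.frame(table),
            all(c(group_col, "has_splicing") %in% colnames(table)))
  rows <- table[[group_col]] == group
  if (!any(rows)) {
    warning(sprintf("empty group '%s'", group), call. = FALSE)
    return(NA_real_)
  }
  100 * mean(table$has_splicing[rows])
}

.comparison_row <- function(contrast, n_a, n_b, statistic, value, p_value,
                            sidedness = "two_sided", note = NA_character_) {
  data.frame(contrast = contrast, n_a = n_a, n_b = n_b,
             statistic = statistic, value = value, p_value = p_value,
             sidedness = sidedness, note = note, stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' U statistic with midrank tie handling. The p-value is exact (full
#' enumeration) when the pooled sample has at most `exact_max` observations
#' and no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used -- the approximation is the
#' default at cohort scale.
#'
#' @param values_a,values_b Numeric vectors; `NA`s are dropped.
#' @param sidedness `"two_sided"` (default), `"greater"` or `"less"`
#'   (alternatives on group A relative to group B).
#' @param exact_max Largest pooled size for which the exact distribution is
#'   enumerated (when there are no ties).
#' @param contrast Label for the report row.
#'
#' @return A one-row comparison data frame: `contrast`, `n_a`, `n_b`,
#'   `statistic` (`"mann_whitney_U"`), `value` (U for group A), `p_value`,
#'   `sidedness`.
#' @export
mann_whitney_u <- function(values_a, values_b, sidedness = "two_sided",
                           exact_max = 12L, contrast = "A_vs_B") {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0L)
    stop("input error: no non-NA values in group A", call. = FALSE)
  if (length(b) == 0L)
    stop("input error: no non-NA values in group B", call. = FALSE)
  alternative <- switch(sidedness, two_sided = "two.sided",
                        greater = "greater", less = "less",
                        stop("sidedness must be two_sided, greater or less",
                             call. = FALSE))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= exact_max
  # U with midranks, computed directly; wilcox.test's W equals this U
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(a) * length(b) == 0 || (max(c(a, b)) == min(c(a, b)))) {
    # all values identical: U is its null mean, no evidence either way
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                              exact = exact, correct = TRUE))
    stopifnot(isTRUE(all.equal(unname(wt$statistic), u)))
    p <- wt$p.value
  }
  .comparison_row(contrast, length(a), length(b), "mann_whitney_U", u,
                  min(p, 1), sidedness)
}

#' One-way ANOVA across factor levels
#'
#' `F = MS_between / MS_within` with the standard degrees of freedom and the
#' upper-tail F p-value. Degenerate inputs follow explicit conventions:
#' perfectly separated groups with zero within-group variance give
#' `F = Inf`, `p = 0`; zero variance both between and within gives
#' `p = NA`.
#'
#' @param values_by_level Named list of numeric vectors (one per level), or
#'   a data frame with `value` and `level` columns. `NA`s are dropped.
#' @param contrast Label for the report row.
#'
#' @return A one-row comparison data frame with `statistic = "anova_F"`.
#' @export
oneway_anova <- function(values_by_level, contrast = "anova") {
  if (is.data.frame(values_by_level))
    values_by_level <- split(values_by_level$value, values_by_level$level)
  values_by_level <- lapply(values_by_level, function(v) v[!is.na(v)])
  values_by_level <- values_by_level[lengths(values_by_level) > 0L]
  k <- length(values_by_level)
  if (k < 2L)
    stop("input error: one-way ANOVA needs at least two levels with values",
         call. = FALSE)
  if (!any(lengths(values_by_level) >= 2L))
    stop("input error: at least one level must have two or more values",
         call. = FALSE)
  y <- unlist(values_by_level, use.names = FALSE)
  g <- factor(rep(names(values_by_level), lengths(values_by_level)))
  n <- length(y)

  ss_within <- sum(unlist(lapply(values_by_level,
                                 function(v) sum((v - mean(v))^2))))
  ss_between <- sum(lengths(values_by_level) *
                      (vapply(values_by_level, mean, numeric(1)) - mean(y))^2)
  if (ss_within <= .Machine$double.eps * sum(y^2 + 1)) {
    if (ss_between <= .Machine$double.eps * sum(y^2 + 1))
      return(.comparison_row(contrast, n, NA_integer_, "anova_F",
                             NA_real_, NA_real_,
                             note = "zero variance within and between"))
    return(.comparison_row(contrast, n, NA_integer_, "anova_F", Inf, 0,
                           note = "zero within-group variance"))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  .comparison_row(contrast, n, NA_integer_, "anova_F",
                  fit[["F value"]][1L], fit[["Pr(>F)"]][1L])
}

#' Rank-sum comparison within strata
#'
#' Runs [mann_whitney_u()] separately within each level of a stratifying
#' column (e.g. sex), comparing the two diagnosis groups on the skipping
#' percentage. Strata with fewer than `min_per_arm` non-NA samples in either
#' arm are reported as skipped, with the reason in the `note` column.
#'
#' @param table Cohort table.
#' @param stratum_col Column to stratify on.
#' @param group_col Diagnosis-group column (must have exactly two levels in
#'   the table, or give `groups`).
#' @param value_col Column compared between the groups.
#' @param groups Optional length-2 vector naming the contrasted groups.
#' @param min_per_arm Minimum non-NA samples per arm (default 3).
#'
#' @return A comparison data frame with one row per stratum level.
#' @export
stratified_compare <- function(table, stratum_col = "sex",
                               group_col = "group",
                               value_col = "pct_skipped", groups = NULL,
                               min_per_arm = 3L) {
  stopifnot(is.data.frame(table),
            all(c(stratum_col, group_col, value_col) %in% colnames(table)))
  groups <- groups %||% sort(unique(table[[group_col]]))
  if (length(groups) != 2L)
    stop("input error: stratified_compare needs exactly two groups",
         call. = FALSE)
  out <- lapply(sort(unique(table[[stratum_col]])), function(level) {
    rows <- table[table[[stratum_col]] == level, , drop = FALSE]
    a <- rows[[value_col]][rows[[group_col]] == groups[1L]]
    b <- rows[[value_col]][rows[[group_col]] == groups[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    label <- sprintf("%s_vs_%s|%s=%s", groups[1L], groups[2L],
                     stratum_col, level)
    if (length(a) < min_per_arm || length(b) < min_per_arm)
      return(.comparison_row(label, length(a), length(b), "mann_whitney_U",
                             NA_real_, NA_real_,
                             note = sprintf("skipped: fewer than %d samples per arm",
                                            min_per_arm)))
    mann_whitney_u(a, b, contrast = label)
  })
  do.call(rbind, out)
}

#' Full case-control statistics for a quantified cohort
#'
#' Reproduces the cohort-level analysis panel: per-group skipping prevalence
#' with a two-proportion test on the difference, the overall Mann-Whitney
#' comparison of the skipping percentage, sex-stratified Mann-Whitney
#' comparisons, and one-way ANOVA of the skipping percentage across APOE
#' genotypes. Samples with `NA` percentages are excluded from rank-sum and
#' ANOVA comparisons but kept in prevalence denominators. No
#' multiple-testing correction is applied across panels (they are reported
#' per panel); a Bonferroni column is emitted for transparency.
#'
#' @param table Quantified cohort table (after [compute_ratio()]) with
#'   `group`, `sex`, `apoe`, `pct_skipped`, `has_splicing` columns.
#' @param groups Length-2 vector of contrasted diagnosis groups (first is
#'   the case group).
#' @param stratify Stratifying column for the per-stratum rank-sum panel
#'   (`NULL` to skip).
#' @param anova_col Factor column for the ANOVA panel (`NULL` to skip).
#'
#' @return A `group_comparison` data frame: one row per panel plus
#'   `prevalence_<group>` rows, with a `p_bonferroni` column.
#' @export
cohort_stats <- function(table, groups = c("AD", "NCI"), stratify = "sex",
                         anova_col = "apoe") {
  stopifnot(is.data.frame(table),
            all(c("group", "pct_skipped", "has_splicing") %in%
                  colnames(table)))
  rows <- list()
  prev <- vapply(groups, function(g) prevalence(table, g), numeric(1))
  for (g in groups) {
    n_g <- sum(table$group == g)
    rows[[paste0("prev_", g)]] <-
      .comparison_row(sprintf("prevalence|%s", g), n_g, NA_integer_,
                      "prevalence", prev[[g]], NA_real_, note = "percent")
  }
  flagged <- vapply(groups, function(g)
    sum(table$has_splicing[table$group == g]), numeric(1))
  sizes <- vapply(groups, function(g) sum(table$group == g), numeric(1))
  pt <- suppressWarnings(stats::prop.test(flagged, sizes))
  rows$prev_diff <- .comparison_row(
    sprintf("%s_vs_%s", groups[1L], groups[2L]), sizes[1L], sizes[2L],
    "prevalence_diff", prev[[1L]] - prev[[2L]], pt$p.value)

  a <- table$pct_skipped[table$group == groups[1L]]
  b <- table$pct_skipped[table$group == groups[2L]]
  rows$mw <- mann_whitney_u(a, b, contrast = sprintf("%s_vs_%s",
                                                     groups[1L], groups[2L]))
  if (!is.null(stratify) && stratify %in% colnames(table))
    rows$strat <- stratified_compare(table, stratum_col = stratify,
                                     groups = groups)
  if (!is.null(anova_col) && anova_col %in% colnames(table)) {
    lv <- split(table$pct_skipped, table[[anova_col]])
    lv <- lapply(lv, function(v) v[!is.na(v)])
    lv <- lv[lengths(lv) > 0L]
    if (length(lv) >= 2L && any(lengths(lv) >= 2L))
      rows$anova <- oneway_anova(lv, contrast = sprintf("across_%s",
                                                        anova_col))
    else
      rows$anova <- .comparison_row(sprintf("across_%s", anova_col),
                                    sum(lengths(lv)), NA_integer_, "anova_F",
                                    NA_real_, NA_real_,
                                    note = "skipped: too few informative levels")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tested <- !is.na(out$p_value)
  out$p_bonferroni <- NA_real_
  out$p_bonferroni[tested] <- pmin(out$p_value[tested] * sum(tested), 1)
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Cohort group comparisons\n")
  df <- as.data.frame(x)
  df$value <- ifelse(is.na(df$value), "NA", sprintf("%.4g", df$value))
  df$p_value <- ifelse(is.na(df$p_value), "NA", sprintf("%.4g", df$p_value))
  df$p_bonferroni <- ifelse(is.na(df$p_bonferroni), "NA",
                            sprintf("%.4g", df$p_bonferroni))
  print(df[, c("contrast", "statistic", "n_a", "n_b", "value", "p_value",
               "p_bonferroni", "note")], row.names = FALSE)
  invisible(x)
}

#' Write a statistics report
#'
#' @param comparisons A comparison data frame ([cohort_stats()] output).
#' @param path Output TSV path.
#' @param provenance Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(comparisons, path, provenance = NULL) {
  .write_tsv(as.data.frame(comparisons), path,
             provenance = provenance %||% "baxsplice group statistics")
  invisible(path)
}
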