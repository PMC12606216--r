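#' Per-participant gameplay metrics
#'
#' Runs the full pipeline on one participant's touch-event log: swipe
#' assembly, zone classification, delivery counts, the direct and indirect
#' transition networks, both sharing scores and their difference.
#'
#' @param events touch-event data.frame (or an assembled `swipes` object).
#' @param zm a [zone_map()].
#' @param participant_id identifier copied into the output row.
#' @param tol,baseline passed to [compute_sharing_score()] and
#'   [normalise_with_baseline()].
#' @param use_touch_id passed to [assemble_swipes()].
#' @return One-row data.frame: `participant_id`, `n_swipes`,
#'   `n_food_delivery`, `n_inter_plate`, `direct_score`, `indirect_score`,
#'   `score_difference` (always `indirect - direct`), `degenerate`.
#' @export
compute_participant_metrics <- function(events, zm = default_zone_map(),
                                        participant_id = NA_character_,
                                        tol = 1e-4, baseline = 0.01,
                                        use_touch_id = "auto") {
  sw <- if (inherits(events, "swipes")) events else
    assemble_swipes(events, use_touch_id = use_touch_id)
  ep <- swipe_endpoints(sw, zm)
  raw <- build_raw_network(ep, zm)
  dirA <- normalise_with_baseline(apply_direct_rules(raw), baseline)
  indA <- normalise_with_baseline(apply_indirect_rules(raw), baseline)
  ds <- compute_sharing_score(dirA, zm, tol = tol)
  is <- compute_sharing_score(indA, zm, tol = tol)
  data.frame(
    participant_id = participant_id,
    n_swipes = sw$n_swipes,
    n_food_delivery = count_food_delivery_swipes(ep, zm),
    n_inter_plate = count_inter_plate_swipes(ep, zm),
    direct_score = ds$score,
    indirect_score = is$score,
    score_difference = sharing_score_difference(is, ds),
    degenerate = ds$degenerate || is$degenerate)
}

#' Metrics table for a simulated cohort
#'
#' Applies [compute_participant_metrics()] to every session of a
#' [simulate_cohort()] result and joins the manifest columns, producing the
#' cohort table the statistical battery consumes.
#'
#' @param cohort result of [simulate_cohort()].
#' @param zm a [zone_map()].
#' @param ... passed to [compute_participant_metrics()].
#' @return data.frame with manifest columns (`group`, `age_months`, `sex`,
#'   `severity`) and metric columns.
#' @export
compute_cohort_metrics <- function(cohort, zm = default_zone_map(), ...) {
  mets <- do.call(rbind, lapply(names(cohort$sessions), function(pid) {
    compute_participant_metrics(cohort$sessions[[pid]]$events, zm,
                                participant_id = pid, ...)
  }))
  merge(cohort$manifest, mets, by = "participant_id", sort = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Two-sided comparison of two independent samples, used for every pairwise
#' group contrast. The p-value is exact for small samples (both sides <= 25,
#' no ties) and uses the normal approximation with tie correction otherwise;
#' the statistic is the Mann-Whitney count of pairs in which the second
#' sample's value precedes the first's in the pooled ordering. Identical
#' constant samples give p = 1.
#'
#' @param x,y numeric samples.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  if (stats::var(c(x, y)) == 0)
    return(list(statistic = nx * ny / 2, p_value = 1,
                method = "wilcoxon rank-sum (degenerate)"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- nx <= 25 && ny <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "wilcoxon rank-sum (exact)"
       else "wilcoxon rank-sum (normal approx.)")
}

#' Spearman rank correlation
#'
#' Monotone-association measure used for all age-trend analyses: Pearson
#' correlation of average ranks. The p-value is exact (permutation
#' distribution) for n <= 9 without ties and uses the t approximation
#' otherwise. Zero variance in either variable leaves the coefficient
#' undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r`, `p_value`, `undefined`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, undefined = TRUE))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9 && !ties))
  list(r = unname(ct$estimate), p_value = ct$p.value, undefined = FALSE)
}

#' Cohort-level nonparametric analysis
#'
#' Reproduces the statistical battery applied to the gameplay metrics: for
#' each requested group contrast and metric, group medians and a two-sided
#' Wilcoxon rank-sum test; for each group and metric, the Spearman
#' correlation with age. Stratified analyses (by sex or severity) reuse the
#' same machinery after combining the stratum into the group label.
#'
#' @param table cohort metrics table from [compute_cohort_metrics()] (needs
#'   `group`, `age_months` and the metric columns; unique participant ids).
#' @param contrasts character vector of contrasts `"groupA:groupB"` (or list
#'   of length-2 character vectors).
#' @param correlates metric column names to analyse.
#' @param stratify_by optional column name; group labels become
#'   `"group/stratum"` and contrasts are interpreted on those labels.
#' @param adjust_method optional p-value adjustment (e.g. `"BH"`) applied
#'   across all rows into an extra `p_adj` column; raw p-values are always
#'   reported.
#' @return Tidy data.frame: `contrast_or_group`, `metric`, `n1`, `n2`,
#'   `median1`, `median2`, `stat`, `p`, `method`.
#' @export
analyze_cohort <- function(table,
                           contrasts = NULL,
                           correlates = c("n_food_delivery", "n_inter_plate",
                                          "direct_score", "indirect_score",
                                          "score_difference"),
                           stratify_by = NULL, adjust_method = NULL) {
  if (anyDuplicated(table$participant_id))
    stop("participant ids must be unique")
  if (!is.null(stratify_by)) {
    if (!stratify_by %in% names(table)) stop("no column '", stratify_by, "'")
    table$group <- paste(table$group, table[[stratify_by]], sep = "/")
  }
  correlates <- intersect(correlates, names(table))
  if (!length(correlates)) stop("no correlate columns found in table")
  if (is.character(contrasts)) contrasts <- strsplit(contrasts, ":")

  rows <- list()
  for (ct in contrasts) {
    g1 <- table[table$group == ct[1], , drop = FALSE]
    g2 <- table[table$group == ct[2], , drop = FALSE]
    if (nrow(g1) < 2 || nrow(g2) < 2) {
      warning("contrast ", paste(ct, collapse = ":"),
              " skipped: a group has fewer than 2 participants")
      next
    }
    for (m in correlates) {
      wt <- wilcoxon_rank_sum(g1[[m]], g2[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        contrast_or_group = paste(ct, collapse = ":"), metric = m,
        n1 = nrow(g1), n2 = nrow(g2),
        median1 = stats::median(g1[[m]]), median2 = stats::median(g2[[m]]),
        stat = wt$statistic, p = wt$p_value, method = wt$method)
    }
  }
  for (g in unique(table$group)) {
    gg <- table[table$group == g, , drop = FALSE]
    if (nrow(gg) < 3) next
    for (m in correlates) {
      sp <- spearman_correlation(gg$age_months, gg[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        contrast_or_group = g, metric = m,
        n1 = nrow(gg), n2 = NA_integer_,
        median1 = stats::median(gg[[m]]), median2 = NA_real_,
        stat = sp$r, p = sp$p_value, method = "spearman vs age")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(adjust_method)) out$p_adj <- stats::p.adjust(out$p,
                                                            adjust_method)
  out
}

#' Notched boxplot summary
#'
#' Median, hinges and the McGill notch interval `median +/- 1.57 * IQR /
#' sqrt(n)`: non-overlapping notches of two boxes indicate different medians
#' at roughly the 5% level. Hinges follow the boxplot convention (medians of
#' the data halves).
#'
#' @param x numeric sample, n >= 1.
#' @return Named list: `median`, `q1`, `q3`, `notch_lo`, `notch_hi`, `n`.
#' @export
notched_box_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop("need at least one observation")
  fn <- stats::fivenum(x)
  med <- fn[3]; q1 <- fn[2]; q3 <- fn[4]
  half <- 1.57 * (q3 - q1) / sqrt(n)
  list(median = med, q1 = q1, q3 = q3,
       notch_lo = med - half, notch_hi = med + half, n = n)
}

#' Notched boxplots of a cohort metric by group
#'
#' Visualisation helper mirroring the analysis figures; requires ggplot2.
#'
#' @param table cohort metrics table.
#' @param metric metric column name.
#' @return A ggplot object.
#' @export
plot_group_boxplots <- function(table, metric = "score_difference") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_boxplot(notch = TRUE) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
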