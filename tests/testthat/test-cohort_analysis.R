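zm <- default_zone_map()

test_that("participant metrics integrate the full pipeline", {
  s <- simulate_session(strategy_profile(
    n_cycles = 10, p_stack = 0, p_direct = 1, offtask_rate = 0,
    tap_rate = 0, within_zone_rate = 0, noise_sd = 0, seed = 111), zm)
  m <- compute_participant_metrics(s$events, zm, participant_id = "p1")
  expect_equal(m$n_food_delivery, 40)
  expect_equal(m$n_inter_plate, 0)
  expect_identical(m$score_difference, 0)
  expect_false(m$degenerate)

  s2 <- simulate_session(strategy_profile(
    n_cycles = 6, p_stack = 1, offtask_rate = 0, tap_rate = 0,
    within_zone_rate = 0, noise_sd = 0, seed = 112), zm)
  m2 <- compute_participant_metrics(s2$events, zm)
  expect_equal(m2$n_inter_plate, 3 * 6)
  expect_gt(m2$score_difference, 0)
  # difference column equals indirect - direct by construction
  expect_equal(m2$score_difference, m2$indirect_score - m2$direct_score,
               tolerance = 1e-12)

  empty <- data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0),
                      phase = character(0))
  m3 <- compute_participant_metrics(empty, zm)
  expect_true(m3$degenerate)
  expect_equal(m3[, c("n_food_delivery", "n_inter_plate", "direct_score",
                      "indirect_score", "score_difference")],
               data.frame(n_food_delivery = 0L, n_inter_plate = 0L,
                          direct_score = 0, indirect_score = 0,
                          score_difference = 0))
})

test_that("wilcoxon wrapper matches exact enumeration and handles edges", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  wt <- wilcoxon_rank_sum(x, y)
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p_value, 0.1)
  expect_equal(wilcoxon_exact_enumeration(x, y), 0.1)
  # a less extreme configuration, still against the enumeration oracle
  x2 <- c(1.2, 3.4, 5.1, 2.2); y2 <- c(2.8, 6.3, 4.4)
  expect_equal(wilcoxon_rank_sum(x2, y2)$p_value,
               wilcoxon_exact_enumeration(x2, y2))
  # symmetry
  expect_equal(wilcoxon_rank_sum(x2, y2)$p_value,
               wilcoxon_rank_sum(y2, x2)$p_value)
  # identical constant samples
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 4))$p_value, 1)
  # identical samples are indistinguishable
  expect_equal(wilcoxon_rank_sum(1:10, 1:10)$p_value, 1, tolerance = 1e-6)
  # large shifted normals are clearly separated
  set.seed(1)
  expect_lt(wilcoxon_rank_sum(rnorm(200), rnorm(200) + 1)$p_value, 1e-3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("spearman wrapper equals Pearson on average ranks, with ties", {
  expect_equal(spearman_correlation(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_correlation(1:10, -(1:10)^3)$r, -1)
  set.seed(2)
  x <- sample(rep(1:6, each = 3)); y <- x + rnorm(18, 0, 2)
  y[c(3, 7)] <- y[c(1, 5)]   # inject ties in y too
  sp <- spearman_correlation(x, y)
  expect_equal(sp$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  # zero variance is flagged undefined
  expect_true(spearman_correlation(rep(1, 5), 1:5)$undefined)
})

test_that("notched box summary follows the McGill convention", {
  nb <- notched_box_summary(1:100)
  expect_equal(nb$median, 50.5)
  expect_equal(nb$q3 - nb$q1, 50)
  expect_equal(nb$notch_hi - nb$median, 7.85)
  one <- notched_box_summary(5)
  expect_equal(one$notch_lo, 5)
  expect_equal(one$notch_hi, 5)
})

test_that("non-overlapping notches imply a significant rank-sum difference", {
  # simulation check of the 5%-level reading of notched boxplots
  set.seed(33)
  hits <- 0; trials <- 0
  for (i in 1:60) {
    a <- rnorm(40); b <- rnorm(40, mean = runif(1, 0.5, 1.2))
    na <- notched_box_summary(a); nb <- notched_box_summary(b)
    disjoint <- na$notch_hi < nb$notch_lo || nb$notch_hi < na$notch_lo
    if (disjoint) {
      trials <- trials + 1
      if (wilcoxon_rank_sum(a, b)$p_value < 0.05) hits <- hits + 1
    }
  }
  expect_gt(trials, 10)
  expect_gte(hits / trials, 0.9)
})

test_that("analyze_cohort emits tidy contrasts and age correlations", {
  set.seed(44)
  tab <- data.frame(
    participant_id = sprintf("p%02d", 1:60),
    group = rep(c("A", "B"), each = 30),
    age_months = runif(60, 30, 72),
    sex = rep(c("F", "M"), 30))
  tab$n_food_delivery <- rpois(60, ifelse(tab$group == "A", 60, 74))
  tab$score_difference <- rnorm(60, ifelse(tab$group == "A", 0.05, 0), 0.02)
  res <- analyze_cohort(tab, contrasts = "A:B",
                        correlates = c("n_food_delivery",
                                       "score_difference"))
  expect_setequal(names(res),
                  c("contrast_or_group", "metric", "n1", "n2", "median1",
                    "median2", "stat", "p", "method"))
  con <- res[res$contrast_or_group == "A:B", ]
  expect_equal(nrow(con), 2)
  expect_equal(con$n1, c(30, 30))
  sp <- res[res$method == "spearman vs age", ]
  expect_equal(nrow(sp), 4)   # 2 groups x 2 metrics
  # identical groups: all contrast p-values 1
  tab2 <- tab
  tab2$group <- "A"
  tab2b <- tab
  tab2b$group <- "B"
  tab2b$participant_id <- sprintf("q%02d", 1:60)
  both <- rbind(tab2, tab2b)
  res2 <- analyze_cohort(both, contrasts = "A:B",
                         correlates = "n_food_delivery")
  expect_equal(res2$p[res2$contrast_or_group == "A:B"], 1, tolerance = 1e-9)
  # stratification reuses the contrast machinery on combined labels
  res3 <- analyze_cohort(tab, contrasts = c("A/F:B/F", "A/M:B/M"),
                         correlates = "n_food_delivery",
                         stratify_by = "sex")
  expect_equal(sum(res3$method != "spearman vs age"), 2)
  # small group skipped with warning
  tab4 <- tab[c(1, 31:60), ]
  expect_warning(analyze_cohort(tab4, contrasts = "A:B",
                                correlates = "n_food_delivery"),
                 "skipped")
  # optional adjustment column
  res5 <- analyze_cohort(tab, contrasts = "A:B",
                         correlates = "n_food_delivery",
                         adjust_method = "BH")
  expect_true("p_adj" %in% names(res5))
  expect_error(analyze_cohort(rbind(tab, tab), contrasts = "A:B"), "unique")
})
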