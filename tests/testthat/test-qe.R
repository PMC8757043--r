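test_that("robust threshold reproduces the hand-computed median/MAD example", {
  v <- c(0.9, 0.8, 0.7, 0.95, 0.85)
  at0 <- robust_threshold(v, 0)
  expect_equal(at0$threshold, 0.85)   # alpha 0: threshold sits at the median
  expect_equal(at0$median, 0.85)
  at01 <- robust_threshold(v, 0.1)
  expect_equal(at01$mad, 0.05)
  expect_equal(at01$threshold, 0.845)
  expect_equal(robust_threshold(v, 1.0)$threshold, 0.80)
})

test_that("non-finite values are excluded from estimation; too few finite errors", {
  got <- robust_threshold(c(0.9, 0.8, NaN, Inf, -Inf, 0.7), 0)
  expect_equal(got$median, 0.8)
  expect_equal(got$n_finite, 3)
  expect_error(robust_threshold(c(0.9, NaN, Inf), 0), "degenerate cohort")
})

test_that("orientation passes dice through and negates hausdorff", {
  expect_equal(orient_values(0.9, "dice"), 0.9)
  expect_equal(orient_values(8.98, "hausdorff"), -8.98)
  expect_identical(orient_values(Inf, "hausdorff"), -Inf)
  expect_true(is.nan(orient_values(NaN, "hausdorff")))
})

test_that("alarms use strict below-threshold comparison and flag NaN/inf", {
  df <- data.frame(
    case_id = paste0("c", 1:5), source_id = "s1", metric = "dice",
    value = c(0.84, 0.845, 0.9, NaN, 0.86), stringsAsFactors = FALSE)
  tab <- values_table(df)
  thr <- structure(data.frame(source_id = "s1", class_name = NA_character_,
                              metric = "dice", alpha = 0.1, median = 0.85,
                              mad = 0.05, threshold = 0.845,
                              stringsAsFactors = FALSE),
                   class = c("threshold_table", "data.frame"))
  rep_ <- raise_alarms(tab, thr)
  f <- rep_$flags
  expect_true(f$flag[f$case_id == "c1"])    # 0.84 < 0.845
  expect_false(f$flag[f$case_id == "c2"])   # equality does not alarm
  expect_true(f$flag[f$case_id == "c4"])    # NaN always alarms
  expect_false(f$flag[f$case_id == "c3"])
})

test_that("risk score accumulates flags per case across metrics", {
  cases <- paste0("c", 1:2)
  df <- rbind(
    data.frame(case_id = cases[1], source_id = paste0("s", 1:5),
               metric = "dice", value = c(0.1, 0.1, 0.1, 0.9, 0.9)),
    data.frame(case_id = cases[1], source_id = paste0("s", 1:5),
               metric = "hausdorff", value = c(90, 90, 90, 90, 1)),
    data.frame(case_id = cases[2], source_id = paste0("s", 1:5),
               metric = "dice", value = 0.9),
    data.frame(case_id = cases[2], source_id = paste0("s", 1:5),
               metric = "hausdorff", value = 1))
  key <- expand.grid(source_id = paste0("s", 1:5),
                     metric = c("dice", "hausdorff"),
                     stringsAsFactors = FALSE)
  thr <- structure(data.frame(source_id = key$source_id,
                              class_name = NA_character_, metric = key$metric,
                              alpha = 0.1, median = 0,
                              mad = 0,
                              threshold = ifelse(key$metric == "dice", 0.5, -50),
                              stringsAsFactors = FALSE),
                   class = c("threshold_table", "data.frame"))
  rep_ <- raise_alarms(values_table(df), thr)
  s <- rep_$summary
  expect_equal(s$risk_score[s$case_id == "c1"], 7)   # 3 dice + 4 hausdorff
  expect_equal(s$dice_flags[s$case_id == "c1"], 3)
  expect_equal(s$hausdorff_flags[s$case_id == "c1"], 4)
  expect_equal(s$risk_score[s$case_id == "c2"], 0)
})

test_that("risk scores are non-increasing in alpha", {
  set.seed(23)
  df <- expand.grid(case_id = paste0("c", 1:12), source_id = paste0("s", 1:3),
                    metric = c("dice", "hausdorff"), stringsAsFactors = FALSE)
  df$value <- ifelse(df$metric == "dice", stats::runif(nrow(df)),
                     stats::rexp(nrow(df), 0.1))
  tab <- values_table(df)
  grid <- default_alpha_grid()
  prev <- NULL
  for (a in grid) {
    rep_ <- raise_alarms(tab, alarm_thresholds(tab, alpha_config(a)))
    risk <- rep_$summary$risk_score[order(rep_$summary$case_id)]
    if (!is.null(prev)) expect_true(all(risk <= prev))
    prev <- risk
  }
})

test_that("shifting one series shifts its threshold and leaves flags unchanged", {
  set.seed(29)
  df <- expand.grid(case_id = paste0("c", 1:10), source_id = c("s1", "s2"),
                    metric = "dice", stringsAsFactors = FALSE)
  df$value <- stats::runif(nrow(df))
  tab <- values_table(df)
  thr1 <- alarm_thresholds(tab, alpha_config(0.3))
  rep1 <- raise_alarms(tab, thr1)
  df2 <- df
  df2$value[df2$source_id == "s1"] <- df2$value[df2$source_id == "s1"] + 0.25
  tab2 <- values_table(df2)
  thr2 <- alarm_thresholds(tab2, alpha_config(0.3))
  rep2 <- raise_alarms(tab2, thr2)
  expect_equal(thr2$threshold[thr2$source_id == "s1"],
               thr1$threshold[thr1$source_id == "s1"] + 0.25)
  expect_identical(rep1$flags$flag, rep2$flags$flag)
})

test_that("with a very large alpha only NaN/inf cells alarm", {
  df <- data.frame(case_id = paste0("c", 1:6), source_id = "s1",
                   metric = "hausdorff",
                   value = c(1, 2, 3, 4, Inf, NaN), stringsAsFactors = FALSE)
  tab <- values_table(df)
  rep_ <- raise_alarms(tab, alarm_thresholds(tab, alpha_config(1e6)))
  f <- rep_$flags
  expect_identical(f$flag, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("threshold rows are recomputable from their stored median and MAD", {
  set.seed(41)
  df <- expand.grid(case_id = paste0("c", 1:9), source_id = paste0("s", 1:4),
                    metric = c("dice", "hausdorff"), stringsAsFactors = FALSE)
  df$value <- stats::runif(nrow(df), 0, 10)
  thr <- alarm_thresholds(values_table(df), alpha_config(0.37))
  expect_equal(thr$threshold, thr$median - thr$mad * thr$alpha)
})

test_that("alpha overrides resolve by specificity with a global fallback", {
  ov <- data.frame(source_id = c("s1", NA), class_name = NA_character_,
                   metric = c(NA, "hausdorff"), alpha = c(0.5, 0.2),
                   stringsAsFactors = FALSE)
  cfg <- alpha_config(0.1, ov)
  df <- expand.grid(case_id = paste0("c", 1:5), source_id = c("s1", "s2"),
                    metric = c("dice", "hausdorff"), stringsAsFactors = FALSE)
  df$value <- seq_len(nrow(df)) / 10
  thr <- alarm_thresholds(values_table(df), cfg)
  expect_equal(thr$alpha[thr$source_id == "s1" & thr$metric == "dice"], 0.5)
  expect_equal(thr$alpha[thr$source_id == "s2" & thr$metric == "hausdorff"], 0.2)
  expect_equal(thr$alpha[thr$source_id == "s2" & thr$metric == "dice"], 0.1)
})

test_that("triage ranks by risk, ties broken by case id", {
  rep_ <- structure(list(summary = data.frame(
    case_id = c("b", "a", "c"), risk_score = c(5L, 5L, 2L))),
    class = "alarm_report")
  r <- rank_cases(rep_)
  expect_identical(r$case_id, c("a", "b", "c"))
  expect_identical(r$rank, 1:3)
})
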