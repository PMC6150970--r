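test_that("confusion matrix counts predicted-vs-observed pairs", {
  obs <- as_mode(c("walk", "walk", "cycle", "train"))
  prd <- as_mode(c("walk", "cycle", "cycle", "train"))
  cm <- confusion_matrix(obs, prd)
  expect_equal(sum(cm), 4)
  expect_equal(cm["walk", "walk"], 1L)
  expect_equal(cm["cycle", "walk"], 1L)
  # perfect prediction is diagonal; constant prediction a single row
  cm_d <- confusion_matrix(obs, obs)
  expect_equal(sum(diag(cm_d)), 4)
  cm_s <- confusion_matrix(obs, rep("stationary", 4))
  expect_equal(sum(cm_s["stationary", ]), 4)
  expect_equal(sum(cm_s) - sum(cm_s["stationary", ]), 0)
  expect_error(confusion_matrix(obs, prd[1:2]), "equal length")
  # brute-force pair counting on random labels
  set.seed(51)
  o <- sample(mode_levels(), 500, replace = TRUE)
  p <- sample(mode_levels(), 500, replace = TRUE)
  cm_r <- confusion_matrix(o, p)
  for (pm in mode_levels()) for (om in mode_levels()) {
    expect_equal(cm_r[pm, om], sum(p == pm & o == om))
  }
})

test_that("per-mode PPV, sensitivity and F1 follow their definitions", {
  cm <- confusion_matrix(rep(mode_levels(), each = 2),
                         rep(mode_levels(), each = 2))
  for (m in mode_levels()) {
    expect_equal(ppv(cm, m), 100)
    expect_equal(sensitivity(cm, m), 100)
  }
  # row (TP=9, 1 false positive) -> PPV 90; column (TP=3, FN=1) -> 75
  o <- c(rep("walk", 9), "cycle", rep("train", 3), "train")
  p <- c(rep("walk", 10), rep("train", 3), "cycle")
  cm2 <- confusion_matrix(o, p)
  expect_equal(ppv(cm2, "walk"), 90)
  expect_equal(sensitivity(cm2, "train"), 75)
  # equivalence with raw-label recomputation on random vectors
  set.seed(52)
  o <- sample(mode_levels(), 400, replace = TRUE)
  p <- sample(mode_levels(), 400, replace = TRUE)
  cm3 <- confusion_matrix(o, p)
  for (m in mode_levels()) {
    ora <- oracle_metrics_from_labels(o, p, m)
    expect_equal(ppv(cm3, m), ora$ppv)
    expect_equal(sensitivity(cm3, m), ora$sensitivity)
  }
  # F1 identities
  expect_equal(f1_score(50, 50), 50)
  expect_equal(f1_score(0, 0), 0)
  ps <- runif(50, 1, 100); ss <- runif(50, 1, 100)
  f <- f1_score(ps, ss)
  expect_true(all(f >= pmin(ps, ss) - 1e-9 & f <= pmax(ps, ss) + 1e-9))
})

test_that("printed per-mode accuracy pairs reproduce the published F1
           scores", {
  # cross-validated train row, manual-comparison cycle row, and the
  # external-study cycle row
  expect_equal(round(f1_score(98.9, 97.5), 1), 98.2)
  expect_equal(round(f1_score(63.0, 94.3), 1), 75.5)
  expect_equal(round(f1_score(70.4, 67.9), 1), 69.1)
})

test_that("mean and active-travel sensitivity are unweighted means of the
           published per-mode values", {
  # cross-validation, manual-comparison and external-study sensitivities
  # in canonical order (walk, cycle, vehicle, train, stationary)
  expect_equal(round(mean_sensitivity(c(92.3, 96.2, 96.9, 97.5, 98.8)), 1),
               96.3)
  expect_equal(round(mean_sensitivity(c(75.6, 94.3, 97.1, 96.6, 97.8)), 1),
               92.3)
  expect_equal(round(mean_sensitivity(c(73.6, 67.9, 98.1, 89.8, 98.1)), 1),
               85.5)
  expect_equal(mean_sensitivity(rep(80, 5)), 80)
  expect_true(is.na(mean_sensitivity(c(NA, 1, 2, 3, 4))))
  expect_equal(active_travel_sensitivity(90, 80), 85)
})

test_that("overall accuracy equals the observed-share-weighted mean
           sensitivity", {
  set.seed(53)
  o <- sample(mode_levels(), 600, replace = TRUE,
              prob = c(0.1, 0.1, 0.2, 0.15, 0.45))
  p <- ifelse(runif(600) < 0.8, o, sample(mode_levels(), 600, TRUE))
  cm <- confusion_matrix(o, p)
  expect_equal(overall_accuracy(cm), 100 * mean(o == p))
  sens <- vapply(mode_levels(), function(m) sensitivity(cm, m), numeric(1))
  share <- colSums(cm) / sum(cm)
  expect_equal(overall_accuracy(cm), sum(share * sens))
  expect_error(overall_accuracy(confusion_matrix(character(0),
                                                 character(0))), "empty")
})

test_that("epoch counts convert to the published wear-time totals", {
  expect_equal(round(epochs_to_hours(12791), 1), 35.5)   # walking epochs
  expect_equal(round(epochs_to_hours(11607), 1), 32.2)   # cycling epochs
  expect_equal(round(epochs_to_hours(59499), 1), 165.3)  # stationary
  expect_equal(round(epochs_to_hours(131573), 1), 365.5) # full training set
  expect_equal(epochs_to_hours(360), 1)
  expect_equal(epochs_to_minutes(6), 1)
})

test_that("time-in-mode summaries conserve totals and reproduce published
           stationary shares", {
  # published mean minutes per participant (manually identified): the two
  # evaluation cohorts sit 83.7% and 86.8% stationary
  enable_min <- c(walk = 245.1, cycle = 30.7, vehicle = 193.7,
                  train = 51.6, stationary = 2675.4)
  stamp_min <- c(walk = 175.0, cycle = 33.9, vehicle = 242.1,
                 train = 13.3, stationary = 3051.4)
  expect_equal(round(proportion_in_mode(enable_min, "stationary"), 1), 83.7)
  expect_equal(round(proportion_in_mode(stamp_min, "stationary"), 1), 86.8)
  # degenerate single-participant case
  labs <- data.frame(participant_id = "p1",
                     observed = rep("stationary", 12))
  tim <- time_in_mode(labs)
  expect_equal(tim$observed_min[tim$mode == "stationary"], 2)
  expect_equal(proportion_in_mode(
    setNames(tim$observed_min, tim$mode), "stationary"), 100)
  # conservation against raw epoch counts over participants
  set.seed(54)
  labs2 <- data.frame(
    participant_id = rep(c("a", "b"), each = 100),
    observed = sample(mode_levels(), 200, replace = TRUE),
    predicted = sample(mode_levels(), 200, replace = TRUE))
  tim2 <- time_in_mode(labs2)
  expect_equal(sum(tim2$observed_min), 200 * 10 / 60 / 2)
  expect_equal(sum(tim2$predicted_min), 200 * 10 / 60 / 2)
  expect_error(time_in_mode(labs2[0, ]), "no participants")
})

test_that("evaluation report renders the metric block", {
  o <- rep(mode_levels(), each = 3)
  lines <- evaluation_report(confusion_matrix(o, o), print = FALSE)
  expect_true(any(grepl("overall accuracy:\\s+100.0", lines)))
  expect_true(any(grepl("stationary", lines)))
})
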