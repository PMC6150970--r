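test_that("fold assignment is participant-level, balanced and seeded", {
  p5 <- sprintf("p%d", 1:5)
  f5 <- assign_participant_folds(p5, k = 5, seed = 1)
  expect_equal(sort(unname(f5)), 1:5)
  f23 <- assign_participant_folds(sprintf("p%d", 1:23), k = 5, seed = 9)
  expect_equal(sort(unname(table(f23)), decreasing = TRUE),
               sort(c(5, 5, 5, 4, 4), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_identical(assign_participant_folds(p5, seed = 4),
                   assign_participant_folds(p5, seed = 4))
  expect_error(assign_participant_folds(p5[1:3], k = 5), "at least 5")
})

test_that("training separates a separable problem and yields normalised
           probabilities", {
  rows <- make_separable_rows(n_per_class = 200, seed = 31)
  fm <- assemble_feature_matrix(rows)
  model <- train_classifier(fm$matrix, fm$labels, gbt_config(seed = 5))
  pr <- predict_modes(model, fm$matrix)
  expect_gte(mean(pr$labels == fm$labels), 0.99)
  expect_equal(rowSums(pr$prob), rep(1, nrow(fm$matrix)), tolerance = 1e-6)
  expect_error(train_classifier(fm$matrix, rep("walk", nrow(fm$matrix))),
               ">= 2 classes")
})

test_that("prediction is the canonical-order argmax with documented
           tie-break", {
  rows <- make_separable_rows(n_per_class = 10, seed = 32)
  fm <- assemble_feature_matrix(rows)
  model <- train_classifier(fm$matrix, fm$labels, gbt_config(seed = 5))
  pr <- predict_modes(model, fm$matrix)
  expect_equal(as.character(pr$labels),
               mode_levels()[max.col(pr$prob, ties.method = "first")])
  # canonical order: (0.1, 0.2, 0.3, 0.2, 0.2) -> vehicle; tie -> walk
  fake <- model
  expect_equal(mode_levels()[which.max(c(0.1, 0.2, 0.3, 0.2, 0.2))],
               "vehicle")
  p_tie <- matrix(c(0.5, 0.5, 0, 0, 0), nrow = 1)
  expect_equal(mode_levels()[max.col(p_tie, ties.method = "first")], "walk")
  # column mismatch refused
  bad <- fm$matrix[, rev(colnames(fm$matrix))]
  expect_error(predict_modes(model, bad), "schema")
})

test_that("fixed seed and single thread reproduce predictions under row
           permutation", {
  rows <- make_separable_rows(n_per_class = 30, seed = 33)
  fm <- assemble_feature_matrix(rows)
  cfg <- gbt_config(seed = 11, subsample = 1)
  m1 <- train_classifier(fm$matrix, fm$labels, cfg)
  set.seed(99)
  perm <- sample(nrow(fm$matrix))
  m2 <- train_classifier(fm$matrix[perm, ], fm$labels[perm], cfg)
  p1 <- predict_modes(m1, fm$matrix)
  p2 <- predict_modes(m2, fm$matrix)
  expect_lt(max(abs(p1$prob - p2$prob)), 1e-6)
  # and two identical runs are bit-identical even with subsampling
  cfg2 <- gbt_config(seed = 11)
  m3 <- train_classifier(fm$matrix, fm$labels, cfg2)
  m4 <- train_classifier(fm$matrix, fm$labels, cfg2)
  expect_identical(predict_modes(m3, fm$matrix)$prob,
                   predict_modes(m4, fm$matrix)$prob)
})

test_that("cross-validation is participant-disjoint and conserves counts", {
  rows <- make_separable_rows(n_per_class = 60, seed = 34)
  cv <- cross_validate(rows, gbt_config(seed = 3, n_rounds = 30), seed = 3)
  expect_equal(sum(cv$pooled), nrow(rows))
  expect_equal(sum(cv$pooled), sum(Reduce(`+`, Filter(Negate(is.null),
                                                      cv$folds))))
  # no participant appears in both train and test of any fold
  for (f in 1:5) {
    test_ids <- names(cv$assignment)[cv$assignment == f]
    in_fold <- cv$predictions$participant_id %in% test_ids
    expect_true(all(!is.na(cv$predictions$predicted[in_fold])))
  }
  expect_equal(length(unique(cv$assignment)), 5)
  # well-separated synthetic data is recovered almost perfectly
  expect_gte(overall_accuracy(cv$pooled), 90)
})

test_that("window-size sweep scores candidates on held-out participants
           and is reproducible", {
  cfg <- sim_config(seed = 41, n_participants = 4, n_days = 1,
                    nonwear_prob = 0)
  sim <- simulate_cohort(cfg)
  eps <- lapply(sim$participants, function(p)
    build_epoch_features(p$accel, p$gps, sim$network,
                         p$truth$participant_id[1]))
  labs <- lapply(sim$participants, function(p)
    data.frame(epoch_start = p$truth$epoch_start, label = p$truth$mode))
  gps <- lapply(sim$participants, `[[`, "gps")
  gb <- gbt_config(seed = 2, n_rounds = 20)
  sweep1 <- window_size_sweep(eps, labs, gps, holdout_ids = "p04",
                              candidate_minutes = c(1, 4), config = gb)
  sweep2 <- window_size_sweep(eps, labs, gps, holdout_ids = "p04",
                              candidate_minutes = c(1, 4), config = gb)
  expect_equal(sweep1$active_travel_f1, sweep2$active_travel_f1)
  expect_true(attr(sweep1, "best") %in% c(1, 4))
  single <- window_size_sweep(eps, labs, gps, holdout_ids = "p04",
                              candidate_minutes = 4, config = gb)
  expect_equal(attr(single, "best"), 4)
  expect_error(window_size_sweep(eps, labs, gps, holdout_ids = "p04",
                                 candidate_minutes = numeric(0)),
               "no candidate")
})

test_that("model files round-trip and refuse foreign schemas", {
  rows <- make_separable_rows(n_per_class = 10, seed = 35)
  fm <- assemble_feature_matrix(rows)
  model <- train_classifier(fm$matrix, fm$labels,
                            gbt_config(seed = 5, n_rounds = 10))
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  loaded <- load_model(path)
  expect_equal(loaded$columns, model$columns)
  expect_equal(loaded$config$n_rounds, 10)
  expect_identical(predict_modes(loaded, fm$matrix)$labels,
                   predict_modes(model, fm$matrix)$labels)
  junk <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), junk,
                       auto_unbox = TRUE)
  expect_error(load_model(junk), "schema")
})
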