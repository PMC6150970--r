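# Five-class gradient-boosted tree classifier. Hyperparameters default to
# a deliberately conservative setting: learning rate 0.1 (below the
# xgboost default of 0.3), 200 boosting rounds, row subsampling 0.2 so
# each tree sees 20% of the data, maximum depth 10 and minimum split loss
# (gamma) 10 — all chosen to limit overfitting. Training is single-thread
# by default, which makes fixed-seed runs reproducible at the label level.

#' Gradient-boosted tree configuration
#'
#' @param learning_rate shrinkage (eta) applied to each tree.
#' @param n_rounds number of boosting rounds.
#' @param subsample fraction of rows sampled per tree.
#' @param max_depth maximum tree depth.
#' @param gamma minimum loss reduction to split (min split loss).
#' @param nthread training threads; 1 (default) is the deterministic
#'   contract.
#' @param seed RNG seed for subsampling.
#' @return List of class `gbt_config`.
#' @export
gbt_config <- function(learning_rate = 0.1, n_rounds = 200, subsample = 0.2,
                       max_depth = 10, gamma = 10, nthread = 1, seed = 1) {
  stopifnot(learning_rate > 0, n_rounds > 0, subsample > 0, subsample <= 1,
            max_depth > 0, gamma >= 0, nthread >= 1)
  structure(list(learning_rate = learning_rate, n_rounds = n_rounds,
                 subsample = subsample, max_depth = max_depth, gamma = gamma,
                 nthread = nthread, seed = as.integer(seed)),
            class = "gbt_config")
}

#' Assign participants to cross-validation folds
#'
#' Seeded shuffle of the participant ids followed by round-robin fold
#' assignment, so folds are at the participant level (no person's epochs
#' ever span train and test) and fold sizes differ by at most one.
#'
#' @param participants character vector of unique participant ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed; same seed, same assignment.
#' @return Named integer vector: participant id -> fold in 1..k.
#' @export
assign_participant_folds <- function(participants, k = 5, seed = 1) {
  participants <- unique(as.character(participants))
  if (length(participants) < k) {
    stop("need at least ", k, " participants for ", k, "-fold assignment")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(participants)
  folds <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  folds[participants]
}

# save/restore global RNG state so seeded internals don't perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train the five-class classifier
#'
#' Fits a multiclass (softprob) gradient-boosted tree to the feature
#' matrix; missing feature values are handled natively by the learner.
#'
#' @param matrix numeric feature matrix (rows = epochs).
#' @param labels mode labels, length `nrow(matrix)`.
#' @param config a [gbt_config()].
#' @return Object of class `travelmode_model`: the fitted booster plus the
#'   column names, class order and config.
#' @export
train_classifier <- function(matrix, labels, config = gbt_config()) {
  labels <- as_mode(labels)
  present <- levels(droplevels(labels))
  if (length(present) < 2) stop("need >= 2 classes to train")
  y <- as.integer(labels) - 1L  # canonical order, 0-based
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(matrix, label = y,
                                 nthread = config$nthread)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "multi:softprob", num_class = length(mode_levels()),
      eta = config$learning_rate, subsample = config$subsample,
      max_depth = config$max_depth, gamma = config$gamma,
      nthread = config$nthread, seed = config$seed),
    data = dtrain, nrounds = config$n_rounds, verbose = 0)
  structure(list(booster = booster, columns = colnames(matrix),
                 classes = mode_levels(), config = config),
            class = "travelmode_model")
}

#' @export
print.travelmode_model <- function(x, ...) {
  cat(sprintf(
    "<travelmode_model: %d features, %d rounds, eta %g, subsample %g>\n",
    length(x$columns), x$config$n_rounds, x$config$learning_rate,
    x$config$subsample))
  invisible(x)
}

#' Predict travel modes for epochs
#'
#' Returns the per-class probabilities and the argmax label per row; exact
#' probability ties are broken towards the earlier mode in canonical
#' order.
#'
#' @param model a `travelmode_model`.
#' @param matrix numeric feature matrix with the training columns.
#' @return List: `labels` (mode factor), `prob` (matrix, columns in
#'   canonical mode order).
#' @export
predict_modes <- function(model, matrix) {
  if (!identical(colnames(matrix), model$columns)) {
    stop("schema error: feature columns do not match the trained model")
  }
  prob <- stats::predict(model$booster, matrix)
  if (!is.matrix(prob)) {
    prob <- base::matrix(prob, ncol = length(model$classes), byrow = TRUE)
  }
  colnames(prob) <- model$classes
  labels <- as_mode(model$classes[max.col(prob, ties.method = "first")])
  list(labels = labels, prob = prob)
}

#' Participant-level k-fold cross-validation
#'
#' Participants are randomly assigned to folds; each fold's epochs are
#' predicted by a model trained on the other folds' epochs only. The
#' pooled confusion matrix is the elementwise sum of the fold matrices,
#' so its total equals the number of labelled rows evaluated.
#'
#' @param rows labelled feature rows (>= k participants).
#' @param config a [gbt_config()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param require_gps passed to [assemble_feature_matrix()].
#' @return List of class `travelmode_cv`: `pooled` confusion matrix,
#'   `folds` (per-fold matrices), `assignment`, and `predictions`
#'   (data.frame of participant, epoch_start, observed, predicted).
#' @export
cross_validate <- function(rows, config = gbt_config(), k = 5, seed = 1,
                           require_gps = FALSE) {
  fm <- assemble_feature_matrix(rows, require_gps = require_gps)
  if (is.null(fm$labels)) stop("cross_validate needs labelled rows")
  keep <- !is.na(fm$labels)
  m <- fm$matrix[keep, , drop = FALSE]
  y <- fm$labels[keep]
  part <- fm$participants[keep]
  assignment <- assign_participant_folds(unique(part), k = k, seed = seed)

  folds <- vector("list", k)
  pred_all <- rep(NA_character_, length(y))
  for (f in seq_len(k)) {
    test_ids <- names(assignment)[assignment == f]
    te <- part %in% test_ids
    if (!any(te)) next
    tr_labels <- droplevels(y[!te])
    if (nlevels(tr_labels) < length(mode_levels())) {
      warning(sprintf("fold %d: training data missing class(es) %s", f,
                      paste(setdiff(mode_levels(), levels(tr_labels)),
                            collapse = ", ")))
    }
    model <- train_classifier(m[!te, , drop = FALSE], y[!te], config)
    pr <- predict_modes(model, m[te, , drop = FALSE])
    pred_all[te] <- as.character(pr$labels)
    folds[[f]] <- confusion_matrix(y[te], pr$labels)
  }
  pooled <- Reduce(`+`, Filter(Negate(is.null), folds))
  structure(list(pooled = pooled, folds = folds, assignment = assignment,
                 predictions = data.frame(
                   participant_id = part, observed = as.character(y),
                   predicted = pred_all)),
            class = "travelmode_cv")
}

#' @export
print.travelmode_cv <- function(x, ...) {
  cat("Participant-level cross-validation\n")
  print(mode_metrics(x$pooled))
  invisible(x)
}

#' Moving-window-size sweep
#'
#' Rebuilds the window features for each candidate window length, trains
#' on the training participants and scores on the held-out participants.
#' The score is the mean of the walk and cycle F1 (accuracy on the active
#' travel modes, which the smoothing is meant to help most); the best
#' candidate is the argmax, ties to the shorter window.
#'
#' @param epochs_by_participant named list: participant id -> epoch
#'   feature table from [build_epoch_features()].
#' @param labels_by_participant named list: participant id -> data.frame
#'   `epoch_start, label` used to label rows after windowing.
#' @param gps_by_participant named list: participant id -> GPS fixes (for
#'   the travelled-distance features); entries may be NULL.
#' @param holdout_ids participant ids used for evaluation only.
#' @param candidate_minutes window lengths to try (default 1:5).
#' @param config a [gbt_config()].
#' @return data.frame `window_minutes, active_travel_f1`, with attribute
#'   `best` (the selected window length).
#' @export
window_size_sweep <- function(epochs_by_participant, labels_by_participant,
                              gps_by_participant = NULL,
                              holdout_ids, candidate_minutes = 1:5,
                              config = gbt_config()) {
  if (length(candidate_minutes) == 0) stop("no candidate window sizes")
  ids <- names(epochs_by_participant)
  train_ids <- setdiff(ids, holdout_ids)
  if (length(train_ids) == 0 || length(holdout_ids) == 0) {
    stop("need disjoint, non-empty training and holdout participants")
  }
  build_rows <- function(id, wmin) {
    ep <- epochs_by_participant[[id]]
    rows <- moving_window_stats(ep, window_minutes = wmin)
    gps <- if (!is.null(gps_by_participant)) gps_by_participant[[id]] else NULL
    mid <- rows$epoch_start + 5
    rows[, dist_prev_min_m := distance_travelled(gps, mid, "previous")]
    rows[, dist_next_min_m := distance_travelled(gps, mid, "next")]
    lab <- labels_by_participant[[id]]
    rows[, label := lab$label[match(as.numeric(epoch_start),
                                    as.numeric(lab$epoch_start))]]
    rows
  }
  scores <- vapply(candidate_minutes, function(wmin) {
    tr <- data.table::rbindlist(lapply(train_ids, build_rows, wmin = wmin))
    ho <- data.table::rbindlist(lapply(holdout_ids, build_rows, wmin = wmin))
    ftr <- assemble_feature_matrix(tr)
    fho <- assemble_feature_matrix(ho)
    model <- train_classifier(ftr$matrix, ftr$labels, config)
    pr <- predict_modes(model, fho$matrix)
    cm <- confusion_matrix(fho$labels, pr$labels)
    met <- mode_metrics(cm)
    mean(met$f1[met$mode %in% c("walk", "cycle")], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(window_minutes = candidate_minutes,
                    active_travel_f1 = scores)
  attr(out, "best") <- candidate_minutes[which.max(scores)]
  out
}

#' Save / load a trained model
#'
#' The booster is serialised via xgboost's raw format and stored base64
#' inside a JSON envelope together with the feature column names, class
#' order and configuration; loading refuses a file whose schema does not
#' match the package's.
#'
#' @param model a `travelmode_model`.
#' @param path destination / source.
#' @return `load_model()` returns the `travelmode_model`.
#' @export
save_model <- function(model, path) {
  raw <- xgboost::xgb.save.raw(model$booster)
  payload <- list(
    format = "travelmode_model_v1",
    columns = model$columns, classes = model$classes,
    config = unclass(model$config),
    booster_b64 = jsonlite::base64_enc(raw))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "travelmode_model_v1")) {
    stop("schema error: not a travelmode model file")
  }
  if (!identical(payload$classes, mode_levels())) {
    stop("schema error: class order mismatch")
  }
  booster <- xgboost::xgb.load.raw(
    jsonlite::base64_dec(paste(payload$booster_b64, collapse = "")))
  cfg <- do.call(gbt_config, payload$config[names(payload$config) != "seed"])
  cfg$seed <- as.integer(payload$config$seed)
  structure(list(booster = booster, columns = payload$columns,
                 classes = payload$classes, config = cfg),
            class = "travelmode_model")
}
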