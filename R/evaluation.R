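# Test-performance measures: per-mode positive predictive value,
# sensitivity and F1, overall accuracy, mean and active-travel mean
# sensitivity, epoch-count unit conversions and time-in-mode summaries.
# Metrics with an empty row/column are reported as NA, never 0, so means
# over missing values stay missing instead of being silently deflated.

#' Confusion matrix of predicted vs observed modes
#'
#' Rows are the predicted mode, columns the observed mode, both in
#' canonical order; cell (p, o) counts epochs predicted p and observed o.
#'
#' @param observed,predicted equal-length vectors of mode labels.
#' @return 5x5 integer matrix of class `travelmode_cm`.
#' @export
confusion_matrix <- function(observed, predicted) {
  observed <- as_mode(observed)
  predicted <- as_mode(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  m <- table(predicted = predicted, observed = observed)
  m <- base::matrix(as.integer(m), nrow = length(mode_levels()),
                    dimnames = list(predicted = mode_levels(),
                                    observed = mode_levels()))
  structure(m, class = c("travelmode_cm", class(m)))
}

#' @export
print.travelmode_cm <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = observed)\n")
  print(unclass(x))
  invisible(x)
}

#' Positive predictive value per mode
#'
#' The percentage of epochs predicted as `mode` that were observed as
#' that mode: 100 * true positives / (true + false positives), i.e. the
#' diagonal cell over its row sum. NA when nothing was predicted as the
#' mode.
#'
#' @param cm a [confusion_matrix()].
#' @param mode one of [mode_levels()].
#' @return Percentage in \[0, 100\] or NA.
#' @export
ppv <- function(cm, mode) {
  mode <- match.arg(mode, mode_levels())
  rs <- sum(cm[mode, ])
  if (rs == 0) return(NA_real_)
  100 * cm[mode, mode] / rs
}

#' Sensitivity (recall) per mode
#'
#' The percentage of epochs observed as `mode` that were predicted as
#' that mode: 100 * true positives / (true positives + false negatives),
#' i.e. the diagonal cell over its column sum. NA when the mode was never
#' observed.
#'
#' @inheritParams ppv
#' @return Percentage in \[0, 100\] or NA.
#' @export
sensitivity <- function(cm, mode) {
  mode <- match.arg(mode, mode_levels())
  cs <- sum(cm[, mode])
  if (cs == 0) return(NA_real_)
  100 * cm[mode, mode] / cs
}

#' F1 score from PPV and sensitivity
#'
#' Harmonic mean of the two percentages; 0 when both are 0, NA if either
#' is missing.
#'
#' @param ppv_pct,sensitivity_pct percentages.
#' @return Percentage (vectorised).
#' @export
f1_score <- function(ppv_pct, sensitivity_pct) {
  ifelse(is.na(ppv_pct) | is.na(sensitivity_pct), NA_real_,
         ifelse(ppv_pct + sensitivity_pct == 0, 0,
                2 * ppv_pct * sensitivity_pct / (ppv_pct + sensitivity_pct)))
}

#' Overall accuracy
#'
#' Percentage of epochs predicted correctly: 100 * trace / total.
#'
#' @param cm a [confusion_matrix()].
#' @return Percentage.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Mean sensitivity across the five modes
#'
#' Unweighted arithmetic mean of the per-mode sensitivities; missing if
#' any mode's sensitivity is missing.
#'
#' @param sens numeric vector of five per-mode sensitivities (%).
#' @return Percentage or NA.
#' @export
mean_sensitivity <- function(sens) {
  if (length(sens) != 5) stop("need five per-mode sensitivities")
  if (anyNA(sens)) return(NA_real_)
  mean(sens)
}

#' Mean active-travel sensitivity
#'
#' Unweighted mean of the walk and cycle sensitivities.
#'
#' @param walk_sens,cycle_sens percentages.
#' @return Percentage or NA.
#' @export
active_travel_sensitivity <- function(walk_sens, cycle_sens) {
  if (is.na(walk_sens) || is.na(cycle_sens)) return(NA_real_)
  mean(c(walk_sens, cycle_sens))
}

#' Per-mode metric table for a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame `mode, ppv, sensitivity, f1` (%) with attributes
#'   `overall_accuracy`, `mean_sensitivity`,
#'   `active_travel_sensitivity`.
#' @export
mode_metrics <- function(cm) {
  p <- vapply(mode_levels(), function(m) ppv(cm, m), numeric(1))
  s <- vapply(mode_levels(), function(m) sensitivity(cm, m), numeric(1))
  out <- data.frame(mode = mode_levels(), ppv = p, sensitivity = s,
                    f1 = f1_score(p, s), row.names = NULL)
  attr(out, "overall_accuracy") <- overall_accuracy(cm)
  attr(out, "mean_sensitivity") <- if (anyNA(s)) NA_real_ else mean(s)
  attr(out, "active_travel_sensitivity") <-
    active_travel_sensitivity(s[["walk"]], s[["cycle"]])
  out
}

#' Convert epoch counts to hours / minutes
#'
#' One epoch is 10 s; counts convert directly to wall time.
#'
#' @param n_epochs non-negative epoch count (vectorised).
#' @param epoch_s epoch length in seconds.
#' @return Hours (resp. minutes).
#' @export
epochs_to_hours <- function(n_epochs, epoch_s = 10) {
  stopifnot(all(n_epochs >= 0))
  n_epochs * epoch_s / 3600
}

#' @rdname epochs_to_hours
#' @export
epochs_to_minutes <- function(n_epochs, epoch_s = 10) {
  stopifnot(all(n_epochs >= 0))
  n_epochs * epoch_s / 60
}

#' Time observed and predicted per participant in each mode
#'
#' Mean minutes per participant spent in each mode, for the observed and
#' (optionally) the predicted label streams. Row sums over modes conserve
#' each stream's total evaluated time.
#'
#' @param labels data.frame with `participant_id`, `observed`, and
#'   optionally `predicted` mode labels (one row per epoch).
#' @param epoch_s epoch length in seconds.
#' @return data.frame `mode, observed_min, predicted_min` (predicted NA
#'   when absent), mean minutes per participant.
#' @export
time_in_mode <- function(labels, epoch_s = 10) {
  if (nrow(labels) == 0 || length(unique(labels$participant_id)) == 0) {
    stop("no participants")
  }
  n_part <- length(unique(labels$participant_id))
  per_mode <- function(v) {
    counts <- table(factor(as.character(v), levels = mode_levels()))
    as.numeric(counts) * epoch_s / 60 / n_part
  }
  out <- data.frame(mode = mode_levels(),
                    observed_min = per_mode(labels$observed))
  out$predicted_min <- if ("predicted" %in% names(labels)) {
    per_mode(labels$predicted)
  } else NA_real_
  out
}

#' Share of time in one mode
#'
#' @param minutes named or ordered numeric vector of per-mode minutes (in
#'   canonical mode order when unnamed).
#' @param mode one of [mode_levels()].
#' @return Percentage of total time spent in `mode`.
#' @export
proportion_in_mode <- function(minutes, mode) {
  mode <- match.arg(mode, mode_levels())
  if (is.null(names(minutes))) names(minutes) <- mode_levels()
  100 * minutes[[mode]] / sum(minutes)
}

#' Render an evaluation report
#'
#' Human-readable text block: the confusion matrix, the per-mode metric
#' table (1 d.p., half-up) and the summary accuracies.
#'
#' @param cm a [confusion_matrix()].
#' @return Character vector of report lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print emit to the console.
#' @export
evaluation_report <- function(cm, print = TRUE) {
  met <- mode_metrics(cm)
  r1 <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", round(x, 1)))
  lines <- c(
    "Confusion matrix (rows = predicted, columns = observed)",
    utils::capture.output(print(unclass(cm))),
    "",
    sprintf("%-11s %8s %12s %8s", "mode", "PPV", "sensitivity", "F1"),
    sprintf("%-11s %8s %12s %8s", met$mode, r1(met$ppv),
            r1(met$sensitivity), r1(met$f1)),
    "",
    sprintf("overall accuracy:          %s", r1(attr(met, "overall_accuracy"))),
    sprintf("mean sensitivity:          %s", r1(attr(met, "mean_sensitivity"))),
    sprintf("active travel sensitivity: %s",
            r1(attr(met, "active_travel_sensitivity"))))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
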