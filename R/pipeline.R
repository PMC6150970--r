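# End-to-end wiring: raw streams -> labelled feature rows -> CV report.

#' Build labelled feature rows for a simulated cohort
#'
#' Runs the full feature pipeline (epoch features, moving windows,
#' travelled distances) for every participant of a [simulate_cohort()]
#' result and attaches the ground-truth labels.
#'
#' @param sim result of [simulate_cohort()].
#' @param config the [sim_config()] used.
#' @param window_minutes moving-window length.
#' @return data.table of labelled feature rows, all participants.
#' @export
cohort_features <- function(sim, config, window_minutes = 4) {
  rows <- data.table::rbindlist(lapply(names(sim$participants), function(id) {
    p <- sim$participants[[id]]
    participant_features(p$accel, p$gps, sim$network, id,
                         sample_rate_hz = config$sample_rate_hz,
                         window_minutes = window_minutes)
  }))
  label_rows_from_truth(rows, sim$truth)
}

#' Simulate, extract features and cross-validate in one call
#'
#' The package's main study loop on synthetic data: simulate a labelled
#' cohort, build the classifier features, and run participant-level
#' five-fold cross-validation.
#'
#' @param config a [sim_config()].
#' @param gbt a [gbt_config()].
#' @param window_minutes moving-window length.
#' @param k folds.
#' @return The `travelmode_cv` result; the labelled rows are attached as
#'   attribute `rows`.
#' @export
run_pipeline <- function(config = sim_config(), gbt = gbt_config(),
                         window_minutes = 4, k = 5) {
  sim <- simulate_cohort(config)
  rows <- cohort_features(sim, config, window_minutes)
  cv <- cross_validate(rows, config = gbt, k = k, seed = config$seed)
  attr(cv, "rows") <- rows
  cv
}
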