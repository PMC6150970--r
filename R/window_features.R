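# Four-minute moving-window smoothing of the epoch features, plus the
# distance-travelled-over-previous/next-minute features. Windows are
# centred (+/- half the window) and never cross a gap in the epoch grid:
# travel variation (traffic lights, road crossings, in-train GPS loss) is
# smoothed, device-off gaps are not.

# epoch-level feature columns that get windowed statistics
.accel_feature_cols <- function() {
  as.vector(outer(c("mad", "p10", "p90", "skew", "kurt", "fftmean"),
                  c("x", "y", "z"), paste, sep = "_"))
}

.windowed_base_cols <- function() c(.accel_feature_cols(), "speed_kmh")

#' Moving-window statistics over epoch features
#'
#' For each epoch the window is every epoch of the same contiguous
#' segment whose start lies within +/- `window_minutes / 2` of this
#' epoch's start (a gap of more than one epoch in the 10-s grid breaks
#' contiguity; windows shrink at segment edges). Over that window the
#' mean, standard deviation, and 10th and 90th percentiles of the 18
#' per-axis accelerometer features and of speed are added (suffixes
#' `_wmean`, `_wsd`, `_wp10`, `_wp90`), together with the window mean
#' sumSNR and window mean rail distance. Epochs without GPS contribute
#' only their accelerometer features (GPS-derived window stats ignore
#' them via NA removal).
#'
#' @param epochs data.table/data.frame from [build_epoch_features()],
#'   sorted, single participant.
#' @param window_minutes window length in minutes (default 4).
#' @param epoch_s epoch length in seconds.
#' @return data.table: the input plus windowed columns and `segment_id`.
#' @export
moving_window_stats <- function(epochs, window_minutes = 4, epoch_s = 10) {
  if (window_minutes <= 0) stop("window_minutes must be positive")
  dt <- data.table::as.data.table(epochs)
  data.table::setorder(dt, epoch_start)
  es <- as.numeric(dt$epoch_start)
  n <- length(es)
  dt[, segment_id := if (n > 1) cumsum(c(0, diff(es) > epoch_s)) else 0]

  half <- window_minutes * 60 / 2
  base <- .windowed_base_cols()
  mat <- as.matrix(dt[, c(base, "sum_snr", "rail_dist_m"), with = FALSE])

  stats_names <- c(paste0(rep(base, each = 4),
                          c("_wmean", "_wsd", "_wp10", "_wp90")),
                   "sum_snr_wmean", "rail_dist_m_wmean")
  out <- matrix(NA_real_, nrow = n, ncol = length(stats_names),
                dimnames = list(NULL, stats_names))
  seg <- dt$segment_id
  # first/last row index of each epoch's contiguous segment
  seg_first <- ave(seq_len(n), seg, FUN = min)
  seg_last <- ave(seq_len(n), seg, FUN = max)
  lo_all <- findInterval(es - half, es, left.open = TRUE) + 1L
  hi_all <- findInterval(es + half, es)
  nb <- length(base)
  for (i in seq_len(n)) {
    w <- max(lo_all[i], seg_first[i]):min(hi_all[i], seg_last[i])
    block <- mat[w, , drop = FALSE]
    for (j in seq_len(nb)) {
      v <- block[, j]
      v <- v[is.finite(v)]
      if (length(v) == 0) next
      out[i, (j - 1) * 4 + 1] <- mean(v)
      out[i, (j - 1) * 4 + 2] <- if (length(v) > 1) stats::sd(v) else 0
      qs <- stats::quantile(v, c(0.1, 0.9), type = 7, names = FALSE)
      out[i, (j - 1) * 4 + 3] <- qs[1]
      out[i, (j - 1) * 4 + 4] <- qs[2]
    }
    snr <- block[, nb + 1]; snr <- snr[is.finite(snr)]
    if (length(snr) > 0) out[i, 4 * nb + 1] <- mean(snr)
    rd <- block[, nb + 2]; rd <- rd[is.finite(rd)]
    if (length(rd) > 0) out[i, 4 * nb + 2] <- mean(rd)
  }
  cbind(dt, data.table::as.data.table(out))
}

#' Distance travelled around an instant
#'
#' Sum of haversine hop distances between consecutive GPS fixes whose
#' timestamps both lie within the minute before (`direction = "previous"`,
#' window `[t - span_s, t]`) or after (`direction = "next"`, `[t, t +
#' span_s]`) the instant. Fewer than two fixes in the span gives 0.
#'
#' @param fixes sorted data.frame with `timestamp`, `lat`, `lon`.
#' @param t POSIXct instant (vectorised).
#' @param direction `"previous"` or `"next"`.
#' @param span_s span in seconds (default 60).
#' @return Numeric vector of metres.
#' @export
distance_travelled <- function(fixes, t, direction = c("previous", "next"),
                               span_s = 60) {
  direction <- match.arg(direction)
  tn <- as.numeric(t)
  if (is.null(fixes) || nrow(fixes) < 2) return(rep(0, length(tn)))
  ft <- as.numeric(fixes$timestamp)
  # hop i covers fixes i..i+1; cumulative distance up to fix k
  hops <- haversine_m(fixes$lat[-nrow(fixes)], fixes$lon[-nrow(fixes)],
                      fixes$lat[-1], fixes$lon[-1])
  cum <- c(0, cumsum(hops))
  lo_t <- if (direction == "previous") tn - span_s else tn
  hi_t <- if (direction == "previous") tn else tn + span_s
  first <- findInterval(lo_t, ft, left.open = TRUE) + 1L # first fix >= lo
  last <- findInterval(hi_t, ft)                         # last fix <= hi
  d <- ifelse(last - first >= 1, cum[pmax(last, 1)] - cum[pmin(first, length(cum))],
              0)
  pmax(d, 0)
}

#' Full per-participant feature rows
#'
#' Convenience wrapper: epoch features, moving-window smoothing and the
#' previous/next-minute travelled distances for one participant's raw
#' streams.
#'
#' @inheritParams build_epoch_features
#' @param window_minutes moving-window length in minutes.
#' @return data.table of classifier-ready feature rows.
#' @export
participant_features <- function(accel, gps = NULL, network = NULL,
                                 participant_id = "p1",
                                 sample_rate_hz = 30, epoch_s = 10,
                                 window_minutes = 4) {
  ep <- build_epoch_features(accel, gps, network, participant_id,
                             sample_rate_hz, epoch_s)
  if (nrow(ep) == 0) return(ep)
  rows <- moving_window_stats(ep, window_minutes, epoch_s)
  mid <- rows$epoch_start + epoch_s / 2
  rows[, dist_prev_min_m := distance_travelled(gps, mid, "previous")]
  rows[, dist_next_min_m := distance_travelled(gps, mid, "next")]
  rows[]
}

#' Classifier feature column order
#'
#' The fixed, documented column order of the numeric feature matrix.
#'
#' @return Character vector of column names.
#' @export
feature_matrix_columns <- function() {
  base <- .windowed_base_cols()
  c(.accel_feature_cols(), "speed_kmh", "sum_snr", "rail_dist_m",
    paste0(rep(base, each = 4), c("_wmean", "_wsd", "_wp10", "_wp90")),
    "sum_snr_wmean", "rail_dist_m_wmean",
    "dist_prev_min_m", "dist_next_min_m")
}

#' Assemble the numeric feature matrix
#'
#' Drops non-wear rows (and, when `require_gps`, rows without a GPS fix),
#' then extracts the numeric feature columns in the fixed order of
#' [feature_matrix_columns()]. GPS-derived values that are absent stay NA
#' — the tree learner handles missing values natively.
#'
#' @param rows feature rows from [participant_features()] (any number of
#'   participants bound together).
#' @param require_gps drop rows lacking a GPS fix instead of passing NA.
#' @return List: `matrix` (numeric), `labels` (mode factor or NULL),
#'   `participants` (id per row), `columns`.
#' @export
assemble_feature_matrix <- function(rows, require_gps = FALSE) {
  dt <- data.table::as.data.table(rows)
  n_in <- nrow(dt)
  dt <- dt[nonwear == FALSE]
  if (require_gps) dt <- dt[has_gps == TRUE]
  if (nrow(dt) == 0) stop("no rows left after filtering")
  cols <- feature_matrix_columns()
  missing_cols <- setdiff(cols, names(dt))
  if (length(missing_cols) > 0) {
    stop("schema error: missing feature column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(dt[, cols, with = FALSE])
  labels <- NULL
  if ("label" %in% names(dt) && !all(is.na(dt$label))) {
    labels <- as_mode(dt$label)
  }
  list(matrix = m, labels = labels,
       participants = as.character(dt$participant_id), columns = cols,
       n_input = n_in, n_kept = nrow(dt))
}
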