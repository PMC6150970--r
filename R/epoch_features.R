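# Per-epoch summaries of raw tri-axial accelerometry, GPS merge, sumSNR
# and non-wear flagging. An epoch is a fixed 10-s bin aligned to the UTC
# 10-s grid (timestamps floored); the epoch is the unit of classification.

#' Median absolute deviation from the median
#'
#' `median(|v - median(v)|)` with no consistency scaling factor (the usual
#' 1.4826 normal-consistency constant is deliberately not applied).
#'
#' @param values non-empty numeric vector.
#' @return Non-negative scalar in the units of `values`.
#' @export
mad_from_median <- function(values) {
  if (length(values) == 0) stop("mad_from_median: empty input")
  stats::median(abs(values - stats::median(values)))
}

#' Linear-interpolation percentile
#'
#' Type-7 quantile (the R default), exposed for the 10th and 90th
#' percentile epoch features.
#'
#' @param values non-empty numeric vector.
#' @param q percentile in \[0, 100\].
#' @return Scalar percentile.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0) stop("percentile: empty input")
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Moment-based skewness (Fisher-Pearson g1)
#'
#' g1 = m3 / m2^(3/2) with central moments over n. Zero-variance input
#' returns 0 by convention.
#'
#' @param values numeric vector with at least 3 values.
#' @return Unitless scalar.
#' @export
skewness_g1 <- function(values) {
  n <- length(values)
  if (n < 3) stop("skewness_g1: need >= 3 values")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Moment-based excess kurtosis (g2)
#'
#' g2 = m4 / m2^2 - 3 with central moments over n. Zero-variance input
#' returns 0 by convention.
#'
#' @param values numeric vector with at least 3 values.
#' @return Unitless scalar.
#' @export
kurtosis_g2 <- function(values) {
  n <- length(values)
  if (n < 3) stop("kurtosis_g2: need >= 3 values")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^4) / m2^2 - 3
}

#' Mean FFT strength of an epoch signal
#'
#' The mean one-sided magnitude of the discrete Fourier transform of the
#' mean-subtracted signal, normalised by the sequence length. Removing the
#' DC component first keeps the constant gravity offset out of the
#' feature, so it reflects oscillatory movement only.
#'
#' @param values numeric vector with at least 8 samples.
#' @param rate_hz sampling rate (recorded for documentation; the statistic
#'   itself is rate-free).
#' @return Non-negative scalar in the units of `values`.
#' @export
fft_mean_strength <- function(values, rate_hz = 30) {
  n <- length(values)
  if (n < 8) stop("fft_mean_strength: need >= 8 samples")
  spec <- Mod(stats::fft(values - mean(values))) / n
  # one-sided: bins 2 .. floor(n/2)+1 (DC excluded)
  mean(spec[2:(floor(n / 2) + 1)])
}

#' Sum of per-satellite signal-to-noise ratios
#'
#' @param sat_snr numeric vector of SNR values (dB-Hz); an empty vector
#'   (no satellites) gives 0.
#' @return Non-negative scalar sumSNR.
#' @export
sum_snr <- function(sat_snr) {
  if (length(sat_snr) == 0) return(0)
  sum(sat_snr)
}

#' Resolve epoch speed from a GPS fix
#'
#' The device-reported speed when present; otherwise the haversine
#' distance from the previous fix divided by the elapsed time. With no
#' previous fix (or a non-positive time step) the fallback is 0.
#'
#' @param fix one-row data.frame/list with `timestamp`, `lat`, `lon` and
#'   optionally `device_speed` (km/h, may be NA).
#' @param prev_fix previous fix in the same form, or NULL.
#' @return Speed in km/h.
#' @export
resolve_speed <- function(fix, prev_fix = NULL) {
  if (!is.null(fix$device_speed) && length(fix$device_speed) == 1 &&
      is.finite(fix$device_speed)) {
    return(as.numeric(fix$device_speed))
  }
  if (is.null(prev_fix)) return(0)
  dt <- as.numeric(fix$timestamp) - as.numeric(prev_fix$timestamp)
  if (dt <= 0) {
    warning("resolve_speed: non-positive time step, returning 0")
    return(0)
  }
  d <- haversine_m(prev_fix$lat, prev_fix$lon, fix$lat, fix$lon)
  d / dt * 3.6
}

#' Floor timestamps to the 10-s epoch grid
#'
#' @param timestamp POSIXct vector.
#' @param epoch_s epoch length in seconds (default 10).
#' @return POSIXct vector of epoch starts (UTC).
#' @export
epoch_floor <- function(timestamp, epoch_s = 10) {
  as.POSIXct(floor(as.numeric(timestamp) / epoch_s) * epoch_s,
             origin = "1970-01-01", tz = "UTC")
}

#' Assign accelerometer samples to 10-s epochs
#'
#' Each sample goes to the epoch whose start is its timestamp floored to a
#' 10-s UTC boundary. Epochs holding fewer than 50% of the samples
#' expected at the declared rate are flagged incomplete.
#'
#' @param samples data.frame with `timestamp` (POSIXct, sorted), `ax`,
#'   `ay`, `az` in g.
#' @param sample_rate_hz declared sampling rate.
#' @param epoch_s epoch length, seconds.
#' @return data.table of samples with an `epoch_start` column, plus
#'   attribute `epoch_index`: data.table of `epoch_start`, `n_samples`,
#'   `complete`.
#' @export
segment_epochs <- function(samples, sample_rate_hz = 30, epoch_s = 10) {
  dt <- data.table::as.data.table(samples)
  dt[, epoch_start := epoch_floor(timestamp, epoch_s)]
  idx <- dt[, .(n_samples = .N), by = epoch_start]
  idx[, complete := n_samples >= 0.5 * sample_rate_hz * epoch_s]
  data.table::setattr(dt, "epoch_index", idx)
  dt
}

#' Detect non-wear intervals from raw accelerometry
#'
#' GGIR-style rule: 60-minute windows slide over the trace in 15-minute
#' steps; a window is non-wear when the per-axis sample standard
#' deviation is below 13 mg (0.013 g) on at least two of the three axes.
#' The flagged set is the union of qualifying windows, merged into
#' disjoint intervals. Flag edges are therefore quantised to the step
#' grid.
#'
#' @param samples sorted data.frame with `timestamp`, `ax`, `ay`, `az`.
#' @param window_min window length, minutes.
#' @param step_min step between window starts, minutes.
#' @param sd_threshold_g standard-deviation threshold in g.
#' @param min_axes number of axes that must be below threshold.
#' @return data.frame with POSIXct columns `start`, `end` (possibly zero
#'   rows).
#' @export
detect_nonwear <- function(samples, window_min = 60, step_min = 15,
                           sd_threshold_g = 0.013, min_axes = 2) {
  t <- as.numeric(samples$timestamp)
  n <- length(t)
  win_s <- window_min * 60
  step_s <- step_min * 60
  empty <- data.frame(
    start = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))
  if (n < 2 || t[n] - t[1] < win_s) return(empty)

  # O(1) per-window SD via cumulative sums over the sorted samples
  ax <- samples$ax; ay <- samples$ay; az <- samples$az
  cs <- function(v) c(0, cumsum(v))
  sums <- list(x = cs(ax), y = cs(ay), z = cs(az))
  sqs <- list(x = cs(ax^2), y = cs(ay^2), z = cs(az^2))

  starts <- seq(t[1], t[n] - win_s, by = step_s)
  lo <- findInterval(starts, t, left.open = TRUE) + 1L # first sample >= start
  hi <- findInterval(starts + win_s, t)                # last sample <= end
  win_sd <- function(ss, qq) {
    m <- hi - lo + 1L
    s <- ss[hi + 1L] - ss[lo]
    q <- qq[hi + 1L] - qq[lo]
    ifelse(m >= 2, sqrt(pmax(0, (q - s^2 / m) / (m - 1))), Inf)
  }
  below <- (win_sd(sums$x, sqs$x) < sd_threshold_g) +
    (win_sd(sums$y, sqs$y) < sd_threshold_g) +
    (win_sd(sums$z, sqs$z) < sd_threshold_g)
  flag <- which(below >= min_axes & hi >= lo)
  if (length(flag) == 0) return(empty)

  # merge overlapping/adjacent windows into disjoint intervals
  s <- starts[flag]
  e <- starts[flag] + win_s
  keep_s <- s[1]; out_s <- numeric(0); out_e <- numeric(0); cur_e <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= cur_e) {
        cur_e <- max(cur_e, e[i])
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- s[i]; cur_e <- e[i]
      }
    }
  }
  out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
  data.frame(
    start = as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC"))
}

# TRUE for epochs lying wholly inside any flagged interval
.epoch_in_intervals <- function(epoch_start, intervals, epoch_s = 10) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(epoch_start)))
  es <- as.numeric(epoch_start)
  out <- rep(FALSE, length(es))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (es >= as.numeric(intervals$start[i]) &
                    es + epoch_s <= as.numeric(intervals$end[i]))
  }
  out
}

#' Build per-epoch features from raw accelerometry and GPS
#'
#' Collapses each complete 10-s accelerometer epoch to its per-axis
#' summaries (MAD from the median, 10th/90th percentiles, skewness,
#' excess kurtosis, mean FFT strength), attaches the first GPS fix whose
#' timestamp falls inside the epoch window, and derives speed, sumSNR and
#' distance to the rail network for epochs with GPS. Epochs wholly inside
#' detected non-wear intervals are flagged.
#'
#' @param accel sorted data.frame `timestamp, ax, ay, az` (g).
#' @param gps sorted data.frame of fixes: `timestamp, lat, lon,
#'   device_speed, sat_snr` (list column) — as returned by
#'   [read_gps_log()]; may be NULL.
#' @param network a [rail_network()] or NULL (rail distance then NA).
#' @param participant_id scalar id stored in every row.
#' @param sample_rate_hz accelerometer sampling rate.
#' @param epoch_s epoch length, seconds.
#' @return data.table, one row per complete epoch, sorted by time: id and
#'   epoch_start, 18 per-axis features (`mad_x`, `p10_x`, `p90_x`,
#'   `skew_x`, `kurt_x`, `fftmean_x` and same for y, z), `has_gps`, `lat`,
#'   `lon`, `speed_kmh`, `sum_snr`, `rail_dist_m`, `nonwear`.
#' @export
build_epoch_features <- function(accel, gps = NULL, network = NULL,
                                 participant_id = "p1",
                                 sample_rate_hz = 30, epoch_s = 10) {
  none <- data.table::data.table()
  if (is.null(accel) || nrow(accel) == 0) return(none)
  dt <- segment_epochs(accel, sample_rate_hz, epoch_s)
  idx <- attr(dt, "epoch_index")
  keep <- idx[complete == TRUE, epoch_start]
  if (length(keep) == 0) return(none)

  axis_stats <- function(v) {
    list(mad = mad_from_median(v), p10 = percentile(v, 10),
         p90 = percentile(v, 90), skew = skewness_g1(v),
         kurt = kurtosis_g2(v), fftmean = fft_mean_strength(v))
  }
  feats <- dt[epoch_start %in% keep, {
    sx <- axis_stats(ax); sy <- axis_stats(ay); sz <- axis_stats(az)
    c(stats::setNames(sx, paste0(names(sx), "_x")),
      stats::setNames(sy, paste0(names(sy), "_y")),
      stats::setNames(sz, paste0(names(sz), "_z")))
  }, by = epoch_start]
  feats[, participant_id := participant_id]

  # attach the first fix inside [epoch_start, epoch_start + epoch_s)
  feats[, `:=`(has_gps = FALSE, lat = NA_real_, lon = NA_real_,
               speed_kmh = NA_real_, sum_snr = NA_real_,
               rail_dist_m = NA_real_)]
  if (!is.null(gps) && nrow(gps) > 0) {
    gt <- as.numeric(gps$timestamp)
    ge <- floor(gt / epoch_s) * epoch_s
    first_ix <- !duplicated(ge)
    gfirst <- gps[first_ix, , drop = FALSE]
    gmap <- match(as.numeric(feats$epoch_start), ge[first_ix])
    hit <- !is.na(gmap)
    if (any(hit)) {
      gi <- gmap[hit]
      feats[hit, `:=`(has_gps = TRUE,
                      lat = gfirst$lat[gi], lon = gfirst$lon[gi])]
      # resolved speed: device speed, else distance from previous fix
      spd <- gfirst$device_speed[gi]
      need <- which(!is.finite(spd))
      for (j in need) {
        k <- which(first_ix)[gi[j]]
        spd[j] <- if (k > 1) {
          dtk <- gt[k] - gt[k - 1]
          if (dtk > 0) {
            haversine_m(gps$lat[k - 1], gps$lon[k - 1],
                        gps$lat[k], gps$lon[k]) / dtk * 3.6
          } else 0
        } else 0
      }
      feats[hit, speed_kmh := spd]
      snr_sums <- vapply(gfirst$sat_snr[gi],
                         function(s) sum_snr(s), numeric(1))
      feats[hit, sum_snr := snr_sums]
      if (!is.null(network)) {
        feats[hit, rail_dist_m := distance_to_network_m(lat, lon, network)]
      }
    }
  }

  nw <- detect_nonwear(accel)
  feats[, nonwear := .epoch_in_intervals(epoch_start, nw, epoch_s)]
  data.table::setcolorder(
    feats, c("participant_id", "epoch_start"))
  data.table::setkey(feats, epoch_start)
  feats[]
}
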