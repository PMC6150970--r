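# Independent brute-force oracles and small fixture builders. The
# oracles deliberately use naive enumeration / direct formulas, never the
# package's own code paths.

# --- statistical oracles -------------------------------------------------

oracle_mad <- function(v) {
  s <- sort(v)
  med <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  med(abs(v - med(s)))
}

oracle_skew <- function(v) {
  n <- length(v); m <- sum(v) / n
  m2 <- sum((v - m)^2) / n; m3 <- sum((v - m)^3) / n
  if (m2 == 0) 0 else m3 / m2^1.5
}

oracle_kurt <- function(v) {
  n <- length(v); m <- sum(v) / n
  m2 <- sum((v - m)^2) / n; m4 <- sum((v - m)^4) / n
  if (m2 == 0) 0 else m4 / m2^2 - 3
}

# naive O(n^2) DFT, one-sided mean magnitude excluding DC
oracle_fft_mean <- function(v) {
  n <- length(v)
  x <- v - sum(v) / n
  k_max <- floor(n / 2)
  mags <- vapply(seq_len(k_max), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    sqrt(re^2 + im^2) / n
  }, numeric(1))
  mean(mags)
}

# --- geometry oracles ----------------------------------------------------

oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# distance to a segment by dense sampling along it
oracle_seg_dist <- function(px, py, x1, y1, x2, y2, n = 1e4) {
  t <- seq(0, 1, length.out = n)
  min(sqrt((px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2))
}

# --- metric oracles ------------------------------------------------------

oracle_metrics_from_labels <- function(obs, pred, mode) {
  tp <- sum(obs == mode & pred == mode)
  ppv <- if (sum(pred == mode) == 0) NA_real_ else 100 * tp / sum(pred == mode)
  sens <- if (sum(obs == mode) == 0) NA_real_ else 100 * tp / sum(obs == mode)
  list(ppv = ppv, sensitivity = sens)
}

# --- fixture builders ----------------------------------------------------

# n 10-s epochs of 30 Hz samples starting at a grid-aligned instant
make_accel <- function(n_epochs = 2, rate = 30, start = "2024-06-01 08:00:00",
                       fun = function(t) cbind(sin(2 * pi * 2 * t),
                                               cos(2 * pi * 2 * t),
                                               1 + 0 * t)) {
  t0 <- as.POSIXct(start, tz = "UTC")
  tt <- (seq_len(n_epochs * 10 * rate) - 1) / rate
  a <- fun(tt)
  data.frame(timestamp = t0 + tt, ax = a[, 1], ay = a[, 2], az = a[, 3])
}

make_fix <- function(time, lat = 51.5, lon = -0.1, speed = NA_real_,
                     snr = list(numeric(0))) {
  f <- data.frame(timestamp = as.POSIXct(time, tz = "UTC"), lat = lat,
                  lon = lon, device_speed = speed)
  f$sat_snr <- snr
  f
}

# quick labelled rows for classifier tests: two clearly separated blobs
# per class on two informative features, padded to the full column set
make_separable_rows <- function(n_per_class = 40, seed = 1,
                                classes = mode_levels()) {
  set.seed(seed)
  cols <- feature_matrix_columns()
  n <- n_per_class * length(classes)
  m <- matrix(rnorm(n * length(cols), sd = 0.05), nrow = n,
              dimnames = list(NULL, cols))
  lab <- rep(classes, each = n_per_class)
  m[, "speed_kmh"] <- match(lab, mode_levels()) * 10 + rnorm(n, sd = 0.3)
  m[, "mad_x"] <- match(lab, mode_levels())^2 + rnorm(n, sd = 0.1)
  dt <- data.table::as.data.table(m)
  dt[, participant_id := sprintf("p%02d", rep_len(1:10, n))]
  dt[, epoch_start := as.POSIXct("2024-06-01", tz = "UTC") + seq_len(n) * 10]
  dt[, nonwear := FALSE]
  dt[, has_gps := TRUE]
  dt[, label := lab]
  dt
}
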