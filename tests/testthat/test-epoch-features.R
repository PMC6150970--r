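test_that("MAD from the median is unscaled and translation invariant", {
  expect_equal(mad_from_median(rep(3.7, 10)), 0)
  expect_equal(mad_from_median(c(1, 2, 3, 4, 5)), 1)
  set.seed(1)
  for (i in 1:30) {
    v <- rnorm(sample(5:200, 1))
    expect_equal(mad_from_median(v), oracle_mad(v))
    expect_equal(mad_from_median(v + 17.3), mad_from_median(v))
  }
  expect_error(mad_from_median(numeric(0)), "empty")
})

test_that("percentiles use linear interpolation and are monotone in q", {
  expect_equal(percentile(rep(2.5, 7), 10), 2.5)
  expect_equal(percentile(rep(2.5, 7), 90), 2.5)
  expect_equal(percentile(0:10, 10), 1.0)  # h = (n-1)q+1 lands on index 2
  set.seed(2)
  for (i in 1:30) {
    v <- rnorm(sample(3:100, 1))
    expect_lte(percentile(v, 10), percentile(v, 90))
  }
  expect_error(percentile(numeric(0), 10), "empty")
})

test_that("skewness and kurtosis are the moment estimators with the
           zero-variance convention", {
  expect_equal(skewness_g1(c(-1, 0, 1)), 0)
  expect_equal(skewness_g1(rep(4, 5)), 0)
  expect_equal(kurtosis_g2(rep(4, 5)), 0)
  set.seed(3)
  for (i in 1:30) {
    v <- rnorm(sample(10:300, 1))
    expect_equal(skewness_g1(v), oracle_skew(v), tolerance = 1e-12)
    expect_equal(kurtosis_g2(v), oracle_kurt(v), tolerance = 1e-12)
  }
  # cross-check against an independent implementation of the same
  # estimator family (type-1 moment versions)
  v <- rexp(500)
  expect_equal(skewness_g1(v), e1071::skewness(v, type = 1),
               tolerance = 1e-12)
  expect_equal(kurtosis_g2(v), e1071::kurtosis(v, type = 1),
               tolerance = 1e-12)
  expect_error(skewness_g1(c(1, 2)), ">= 3")
  expect_error(kurtosis_g2(c(1, 2)), ">= 3")
})

test_that("FFT mean strength drops DC, scales linearly and matches a naive
           DFT", {
  expect_equal(fft_mean_strength(rep(5, 300)), 0)
  t <- (0:299) / 30
  s1 <- fft_mean_strength(sin(2 * pi * 3 * t))
  s2 <- fft_mean_strength(2 * sin(2 * pi * 3 * t))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_gt(s1, 0)
  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(300)
    expect_equal(fft_mean_strength(v), oracle_fft_mean(v), tolerance = 1e-9)
  }
  expect_error(fft_mean_strength(rnorm(5)), ">= 8")
})

test_that("sumSNR is a plain sum with empty-list zero", {
  expect_equal(sum_snr(c(38, 42)), 80)
  expect_equal(sum_snr(numeric(0)), 0)
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(0:12, 1), 10, 50)
    expect_equal(sum_snr(v), Reduce(`+`, v, 0))
  }
})

test_that("speed resolution prefers the device and falls back to haversine", {
  f2 <- make_fix("2024-06-01 08:00:10", speed = 12)
  expect_equal(resolve_speed(f2), 12)
  # 100 m in 10 s = 36 km/h
  lat2 <- 51.5 + 100 / 6371000 * 180 / pi
  a <- make_fix("2024-06-01 08:00:00", lat = 51.5)
  b <- make_fix("2024-06-01 08:00:10", lat = lat2)
  expect_equal(resolve_speed(b, a), 36, tolerance = 1e-6)
  dup <- make_fix("2024-06-01 08:00:10", lat = 51.5)
  expect_equal(resolve_speed(dup, a), 0)
  expect_equal(resolve_speed(make_fix("2024-06-01 08:00:00")), 0)
})

test_that("epoch segmentation floors to the 10-s grid and flags
           incomplete epochs", {
  a <- make_accel(1)
  seg <- segment_epochs(a)
  idx <- attr(seg, "epoch_index")
  expect_equal(nrow(idx), 1)
  expect_true(all(idx$complete))
  # samples starting mid-epoch: two epochs, first incomplete
  a2 <- make_accel(2)[181:600, ]  # starts 6 s in: 120 + 300 samples
  idx2 <- attr(segment_epochs(a2), "epoch_index")
  expect_equal(nrow(idx2), 2)
  expect_equal(idx2$complete, c(FALSE, TRUE))
  # random gaps: assignment matches brute-force floor division
  set.seed(6)
  a3 <- make_accel(6)
  a3 <- a3[sort(sample(nrow(a3), 900)), ]
  seg3 <- segment_epochs(a3)
  expect_equal(as.numeric(seg3$epoch_start),
               floor(as.numeric(a3$timestamp) / 10) * 10)
})

test_that("non-wear detection flags sustained low-variability spans", {
  t0 <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC")
  n <- 2 * 3600 * 30
  flat <- data.frame(timestamp = t0 + (seq_len(n) - 1) / 30,
                     ax = 0, ay = 0, az = 1)
  iv <- detect_nonwear(flat)
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$start), as.numeric(t0))
  expect_gte(as.numeric(iv$end) - as.numeric(iv$start), 2 * 3600 - 60 * 60)
  set.seed(7)
  live <- data.frame(timestamp = t0 + (seq_len(n) - 1) / 30,
                     ax = rnorm(n, 0, 0.02), ay = rnorm(n, 0, 0.02),
                     az = 1 + rnorm(n, 0, 0.02))
  expect_equal(nrow(detect_nonwear(live)), 0)
})

test_that("non-wear flags equal a naive window-by-window oracle", {
  # 3-h trace, low rate to keep enumeration cheap: wear / non-wear / wear
  t0 <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC")
  rate <- 5
  n <- 3 * 3600 * rate
  set.seed(8)
  tt <- t0 + (seq_len(n) - 1) / rate
  sdv <- ifelse(tt >= t0 + 45 * 60 & tt < t0 + 150 * 60, 1e-4, 0.05)
  tr <- data.frame(timestamp = tt, ax = rnorm(n, 0, sdv),
                   ay = rnorm(n, 0, sdv), az = 1 + rnorm(n, 0, sdv))
  got <- detect_nonwear(tr)
  # oracle: same 15-min grid, naive sd() per window, union of windows
  starts <- seq(0, 3 * 3600 - 3600, by = 900)
  flagged <- sapply(starts, function(s) {
    w <- tr[as.numeric(tr$timestamp) - as.numeric(t0) >= s &
              as.numeric(tr$timestamp) - as.numeric(t0) <= s + 3600, ]
    sum(c(sd(w$ax), sd(w$ay), sd(w$az)) < 0.013) >= 2
  })
  expect_true(any(flagged))
  oracle_start <- min(starts[flagged])
  oracle_end <- max(starts[flagged]) + 3600
  expect_equal(as.numeric(got$start) - as.numeric(t0), oracle_start)
  expect_equal(as.numeric(got$end) - as.numeric(t0), oracle_end)
  # against a 1-s enumeration the flags agree up to one 15-min step
  starts1s <- seq(0, 3 * 3600 - 3600, by = 60)
  flagged1s <- sapply(starts1s, function(s) {
    w <- tr[as.numeric(tr$timestamp) - as.numeric(t0) >= s &
              as.numeric(tr$timestamp) - as.numeric(t0) <= s + 3600, ]
    sum(c(sd(w$ax), sd(w$ay), sd(w$az)) < 0.013) >= 2
  })
  expect_lte(abs(min(starts1s[flagged1s]) - oracle_start), 900)
  expect_lte(abs(max(starts1s[flagged1s]) + 3600 - oracle_end), 900)
})

test_that("epoch features merge the first in-window GPS fix and apply
           non-wear", {
  a <- make_accel(2)
  fix <- make_fix("2024-06-01 08:00:03", speed = 21, snr = list(c(38, 42)))
  ep <- build_epoch_features(a, fix, participant_id = "px")
  expect_equal(nrow(ep), 2)
  expect_equal(ep$has_gps, c(TRUE, FALSE))
  expect_equal(ep$speed_kmh[1], 21)
  expect_equal(ep$sum_snr[1], 80)
  expect_true(is.na(ep$speed_kmh[2]))
  expect_true(all(!ep$nonwear))
  expect_equal(unique(ep$participant_id), "px")
  # empty accelerometer input gives empty output
  expect_equal(nrow(build_epoch_features(a[0, ], fix)), 0)
  # attached fixes always lie inside their epoch window
  set.seed(9)
  a2 <- make_accel(12)
  fixes <- make_fix(as.POSIXct("2024-06-01 08:00:00", tz = "UTC") +
                      sort(runif(30, 0, 120)),
                    snr = rep(list(numeric(0)), 30))
  ep2 <- build_epoch_features(a2, fixes)
  # recompute which epochs contain a fix, independently
  has <- vapply(as.numeric(ep2$epoch_start), function(e)
    any(as.numeric(fixes$timestamp) >= e &
          as.numeric(fixes$timestamp) < e + 10), logical(1))
  expect_equal(ep2$has_gps, has)
})

test_that("epoch features are translation consistent per axis", {
  a <- make_accel(1, fun = function(t) cbind(0.3 * sin(2 * pi * 2 * t),
                                             0.2 * cos(2 * pi * 1.4 * t),
                                             1 + 0.1 * sin(2 * pi * 3 * t)))
  ep <- build_epoch_features(a)
  a_shift <- a
  a_shift$ax <- a_shift$ax + 0.5
  eps <- build_epoch_features(a_shift)
  expect_equal(eps$p10_x, ep$p10_x + 0.5)
  expect_equal(eps$p90_x, ep$p90_x + 0.5)
  expect_equal(eps$mad_x, ep$mad_x)
  expect_equal(eps$skew_x, ep$skew_x)
  expect_equal(eps$kurt_x, ep$kurt_x)
  expect_equal(eps$fftmean_x, ep$fftmean_x)
})
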