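# Seeded simulator for labelled multimodal days of accelerometer + GPS +
# rail-network data. It reproduces the statistical contrasts the
# classifier exploits: trains and vehicles are fast, walking shows the
# largest accelerometer oscillation, vehicles stop at lights, metal
# enclosures attenuate satellite SNR, trains run along the rail lines and
# lose GPS underground, and non-wear periods are near-constant signal.
# It does not attempt faithful biomechanics or road routing.

.default_mode_params <- function() {
  list(
    stationary = list(speed_mean = 0, speed_sd = 0.12, amp = 0.012,
                      freq_hz = 0.8, noise_g = 0.02, n_sat = 4,
                      snr_mean = 22, snr_sd = 4, dropout = 0.35,
                      gps_jitter_m = 6),
    walk = list(speed_mean = 5, speed_sd = 0.6, amp = 0.35, freq_hz = 2,
                noise_g = 0.05, n_sat = 9, snr_mean = 40, snr_sd = 3,
                dropout = 0.02, gps_jitter_m = 4),
    cycle = list(speed_mean = 16, speed_sd = 2, amp = 0.15, freq_hz = 1.3,
                 noise_g = 0.04, n_sat = 9, snr_mean = 38, snr_sd = 3,
                 dropout = 0.03, gps_jitter_m = 4),
    # vehicle and train share the same low-vibration seated texture: a
    # hip-worn device inside either metal box looks alike; what separates
    # them is speed pattern (stop-go vs sustained), rail distance and SNR
    vehicle = list(speed_mean = 40, speed_sd = 8, amp = 0.03, freq_hz = 7,
                   noise_g = 0.015, n_sat = 6, snr_mean = 28, snr_sd = 4,
                   dropout = 0.10, gps_jitter_m = 6),
    train = list(speed_mean = 55, speed_sd = 10, amp = 0.03, freq_hz = 7,
                 noise_g = 0.015, n_sat = 5, snr_mean = 24, snr_sd = 4,
                 dropout = 0.30, gps_jitter_m = 10))
}

.default_schedule <- function() {
  data.frame(
    mode = c("stationary", "walk", "train", "walk", "stationary",
             "vehicle", "cycle", "stationary"),
    minutes = c(20, 15, 25, 10, 30, 20, 15, 15))
}

#' Simulation configuration
#'
#' Defines the simulated study conditions: cohort size, commute-day
#' schedule and the per-mode speed, accelerometer-texture and satellite
#' SNR regimes. Defaults give clearly separable modes; set
#' `degrade_contrasts = TRUE` for the negative control in which trains
#' take the vehicle speed/SNR regime and leave the rails, removing the
#' cues that distinguish the two motorised modes.
#'
#' @param seed master RNG seed; everything downstream derives from it.
#' @param n_participants cohort size.
#' @param n_days simulated days per participant.
#' @param schedule data.frame `mode, minutes` describing one day; mode
#'   durations must be whole multiples of the 10-s epoch.
#' @param sample_rate_hz accelerometer rate.
#' @param anchor_lat,anchor_lon centre of the simulated area (WGS84).
#' @param extent_km half-width of the area; trajectories and rail lines
#'   stay within it.
#' @param nonwear_prob probability a day ends with a 75-min non-wear
#'   block.
#' @param mode_params per-mode parameter list; see
#'   `travelmode:::.default_mode_params`.
#' @param degrade_contrasts negative control switch (see above).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_participants = 10, n_days = 2,
                       schedule = .default_schedule(),
                       sample_rate_hz = 30,
                       anchor_lat = 51.5, anchor_lon = -0.1,
                       extent_km = 12, nonwear_prob = 0.5,
                       mode_params = .default_mode_params(),
                       degrade_contrasts = FALSE) {
  stopifnot(n_participants >= 1, n_days >= 1,
            all(schedule$mode %in% mode_levels()),
            all(schedule$minutes * 60 %% 10 == 0))
  if (sum(schedule$minutes) > 24 * 60) stop("schedule exceeds day length")
  if (degrade_contrasts) {
    # negative control: trains take the whole vehicle speed/SNR regime
    # (incl. stop-go episodes, applied in .segment_speeds) and leave the
    # rails, removing every cue that separates the two motorised modes
    mode_params$train[c("speed_mean", "speed_sd", "n_sat", "snr_mean",
                        "snr_sd", "dropout", "gps_jitter_m")] <-
      mode_params$vehicle[c("speed_mean", "speed_sd", "n_sat", "snr_mean",
                            "snr_sd", "dropout", "gps_jitter_m")]
  }
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 n_days = n_days, schedule = schedule,
                 sample_rate_hz = sample_rate_hz, anchor_lat = anchor_lat,
                 anchor_lon = anchor_lon, extent_km = extent_km,
                 nonwear_prob = nonwear_prob, mode_params = mode_params,
                 degrade_contrasts = degrade_contrasts),
            class = "sim_config")
}

#' Simulate a rail network
#'
#' A handful of long rail lines crossing the simulated area: each line
#' runs border to border through a point near the centre, with vertices
#' every ~500 m and gentle heading jitter. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param extent_km half-width of the area.
#' @param anchor_lat,anchor_lon area centre.
#' @param n_lines number of rail lines (>= 2).
#' @return A [rail_network()].
#' @export
simulate_rail_network <- function(seed = 1, extent_km = 12,
                                  anchor_lat = 51.5, anchor_lon = -0.1,
                                  n_lines = 3) {
  stopifnot(n_lines >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ext <- extent_km * 1000
  lines <- lapply(seq_len(n_lines), function(i) {
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, -0.3, 0.3) * ext
    cy <- stats::runif(1, -0.3, 0.3) * ext
    step <- 500
    n_steps <- ceiling(2 * ext / step)
    jitter <- cumsum(stats::rnorm(n_steps + 1, 0, 0.03))
    s <- seq(-ext, ext, length.out = n_steps + 1)
    x <- cx + s * cos(theta + jitter)
    y <- cy + s * sin(theta + jitter)
    keep <- abs(x) <= ext & abs(y) <= ext
    x <- x[keep]; y <- y[keep]
    lat <- anchor_lat + y / .EARTH_RADIUS_M * 180 / pi
    lon <- anchor_lon + x / (.EARTH_RADIUS_M * cos(anchor_lat * pi / 180)) *
      180 / pi
    cbind(lon = lon, lat = lat)
  })
  rail_network(lines)
}

# project a network to the simulator's planar frame; per-line cumulative
# arc length for train path interpolation
.network_planar <- function(network, anchor_lat, anchor_lon) {
  lapply(network$polylines, function(m) {
    p <- project_local(m[, "lat"], m[, "lon"], anchor_lat, anchor_lon)
    d <- c(0, cumsum(sqrt(diff(p$x)^2 + diff(p$y)^2)))
    list(x = p$x, y = p$y, arc = d)
  })
}

# position on a planar polyline at arc distance s (bounces at the ends)
.polyline_at <- function(line, s) {
  total <- line$arc[length(line$arc)]
  # reflect s into [0, total] (out-and-back running pattern)
  s <- abs(((s + total) %% (2 * total)) - total)
  i <- findInterval(s, line$arc, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(line$arc) - 1)
  f <- (s - line$arc[i]) / pmax(line$arc[i + 1] - line$arc[i], 1e-9)
  list(x = line$x[i] + f * (line$x[i + 1] - line$x[i]),
       y = line$y[i] + f * (line$y[i + 1] - line$y[i]))
}

# one mode segment's GPS-step speeds (km/h) at 10-s resolution
.segment_speeds <- function(mode, n_steps, mp) {
  p <- mp[[mode]]
  if (mode == "stationary") {
    return(abs(stats::rnorm(n_steps, p$speed_mean, p$speed_sd)))
  }
  v <- numeric(n_steps)
  target <- max(0.5, stats::rnorm(1, p$speed_mean, p$speed_sd))
  stopped <- FALSE
  cur <- target
  for (i in seq_len(n_steps)) {
    if (mode == "vehicle") {
      # stop-go at lights: enter a stop ~ every 8 steps, leave after ~2
      if (stopped) {
        if (stats::runif(1) < 0.4) stopped <- FALSE
      } else if (stats::runif(1) < 0.12) stopped <- TRUE
    }
    cur <- if (stopped) 0.3 * cur else
      0.8 * cur + 0.2 * target + stats::rnorm(1, 0, 0.05 * max(target, 1))
    v[i] <- max(0, cur)
  }
  v
}

# tri-axial accelerometer block for one segment (matrix n x 3, in g)
.segment_accel <- function(mode, n_samples, rate_hz, mp, nonwear = FALSE) {
  if (nonwear) {
    return(cbind(ax = stats::rnorm(n_samples, 0, 3e-4),
                 ay = stats::rnorm(n_samples, 0, 3e-4),
                 az = 1 + stats::rnorm(n_samples, 0, 3e-4)))
  }
  p <- mp[[mode]]
  t <- seq_len(n_samples) / rate_hz
  phase <- stats::runif(3, 0, 2 * pi)
  # amplitude drifts slowly so epochs are not identical
  drift <- 1 + 0.2 * sin(2 * pi * t / 120 + stats::runif(1, 0, 2 * pi))
  osc <- function(scale, ph) {
    scale * p$amp * drift * sin(2 * pi * p$freq_hz * t + ph)
  }
  out <- cbind(
    ax = osc(1.0, phase[1]) + stats::rnorm(n_samples, 0, p$noise_g),
    ay = osc(0.7, phase[2]) + stats::rnorm(n_samples, 0, p$noise_g),
    az = 1 + osc(0.9, phase[3]) + stats::rnorm(n_samples, 0, p$noise_g))
  if (mode == "stationary") {
    # worn-but-sedentary people fidget: short postural-adjustment bursts
    # every couple of minutes keep worn time clearly above the non-wear
    # signal floor (a removed device shows none of these)
    n_bursts <- stats::rpois(1, n_samples / rate_hz / 30)
    for (b in seq_len(n_bursts)) {
      at <- sample.int(n_samples, 1)
      len <- min(round(stats::runif(1, 2, 5) * rate_hz), n_samples - at + 1)
      ix <- at:(at + len - 1)
      tt <- seq_len(len) / rate_hz
      burst <- 0.25 * sin(2 * pi * 3 * tt) * exp(-tt / 2)
      out[ix, ] <- out[ix, ] + burst %o% stats::runif(3, 0.5, 1)
    }
  }
  out
}

#' Simulate one participant's labelled days
#'
#' Integrates the configured day schedule into a trajectory (train
#' segments ride the rail network, other modes follow free paths with a
#' wandering heading), synthesises 30-Hz tri-axial accelerometry with the
#' mode's oscillation texture plus gravity on the z axis, and emits GPS
#' fixes every 10 s with mode-specific satellite counts, SNR levels and
#' dropout. Days flagged for non-wear end with a 75-minute block of
#' near-constant signal and no fixes.
#'
#' @param config a [sim_config()].
#' @param participant_id id stored in the truth table.
#' @param network a [rail_network()]; must be non-NULL if the schedule
#'   contains train segments.
#' @param participant_seed RNG seed for this participant (derived from
#'   the config seed by [simulate_cohort()]).
#' @return List: `accel` (data.frame timestamp/ax/ay/az), `gps` (fix
#'   data.frame as from [read_gps_log()]), `truth` (data.frame
#'   participant_id, epoch_start, mode, nonwear).
#' @export
simulate_participant_week <- function(config, participant_id, network,
                                      participant_seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(participant_seed)
  mp <- config$mode_params
  rate <- config$sample_rate_hz
  epoch_s <- 10
  ext <- config$extent_km * 1000
  planar <- if (!is.null(network)) {
    .network_planar(network, config$anchor_lat, config$anchor_lon)
  } else NULL

  accel_list <- list(); gps_list <- list(); truth_list <- list()
  for (day in seq_len(config$n_days)) {
    day0 <- as.POSIXct(sprintf("2024-06-%02d 08:00:00", day), tz = "UTC")
    sched <- config$schedule
    if (stats::runif(1) < config$nonwear_prob) {
      sched <- rbind(sched, data.frame(mode = "stationary", minutes = 75))
      nonwear_seg <- nrow(sched)
    } else nonwear_seg <- 0L

    # start position: random point well inside the area
    px <- stats::runif(1, -0.4, 0.4) * ext
    py <- stats::runif(1, -0.4, 0.4) * ext
    heading <- stats::runif(1, 0, 2 * pi)
    t_cursor <- 0

    for (si in seq_len(nrow(sched))) {
      mode <- sched$mode[si]
      is_nonwear <- si == nonwear_seg
      dur_s <- sched$minutes[si] * 60
      n_steps <- dur_s / epoch_s
      n_samples <- dur_s * rate
      p <- mp[[mode]]

      # --- trajectory at 10-s steps ---
      speed_mode <- if (mode == "train" && config$degrade_contrasts) {
        "vehicle"
      } else mode
      speeds <- .segment_speeds(speed_mode, n_steps, mp)
      sx <- numeric(n_steps); sy <- numeric(n_steps)
      train_on_rail <- mode == "train" && !is.null(planar) &&
        !config$degrade_contrasts
      if (train_on_rail) {
        line <- planar[[sample.int(length(planar), 1)]]
        # enter at the arc position nearest the current location
        d2 <- (line$x - px)^2 + (line$y - py)^2
        s0 <- line$arc[which.min(d2)]
        dirn <- sample(c(-1, 1), 1)
        s_pos <- s0 + dirn * cumsum(speeds / 3.6 * epoch_s)
        at <- .polyline_at(line, s_pos)
        sx <- at$x; sy <- at$y
        px <- sx[n_steps]; py <- sy[n_steps]
      } else if (mode == "stationary") {
        sx <- rep(px, n_steps); sy <- rep(py, n_steps)
      } else {
        for (i in seq_len(n_steps)) {
          heading <- heading + stats::rnorm(1, 0, 0.12)
          # steer back towards the centre near the border
          if (abs(px) > 0.9 * ext || abs(py) > 0.9 * ext) {
            heading <- atan2(-py, -px)
          }
          d <- speeds[i] / 3.6 * epoch_s
          px <- px + d * cos(heading); py <- py + d * sin(heading)
          sx[i] <- px; sy[i] <- py
        }
      }

      # --- GPS fixes (one per epoch, 1 s into the epoch) ---
      dropout <- if (is_nonwear) 1 else p$dropout
      emit <- stats::runif(n_steps) >= dropout
      if (any(emit)) {
        jx <- stats::rnorm(n_steps, 0, p$gps_jitter_m)
        jy <- stats::rnorm(n_steps, 0, p$gps_jitter_m)
        glat <- config$anchor_lat +
          (sy + jy) / .EARTH_RADIUS_M * 180 / pi
        glon <- config$anchor_lon + (sx + jx) /
          (.EARTH_RADIUS_M * cos(config$anchor_lat * pi / 180)) * 180 / pi
        n_sat <- pmax(3, stats::rpois(n_steps, p$n_sat))
        snr <- lapply(seq_len(n_steps), function(i) {
          pmax(0, round(stats::rnorm(n_sat[i], p$snr_mean, p$snr_sd), 1))
        })
        gf <- data.frame(
          timestamp = day0 + t_cursor + (which(emit) - 1) * epoch_s + 1,
          lat = glat[emit], lon = glon[emit],
          device_speed = pmax(0, speeds[emit] +
                                stats::rnorm(sum(emit), 0, 0.2)),
          n_sat_used = n_sat[emit])
        gf$sat_snr <- snr[emit]
        gps_list[[length(gps_list) + 1]] <- gf
      }

      # --- accelerometer ---
      acc <- .segment_accel(mode, n_samples, rate, mp, nonwear = is_nonwear)
      accel_list[[length(accel_list) + 1]] <- data.frame(
        timestamp = day0 + t_cursor + (seq_len(n_samples) - 1) / rate,
        ax = acc[, 1], ay = acc[, 2], az = acc[, 3])

      # --- truth ---
      truth_list[[length(truth_list) + 1]] <- data.frame(
        participant_id = participant_id,
        epoch_start = day0 + t_cursor + (seq_len(n_steps) - 1) * epoch_s,
        mode = mode, nonwear = is_nonwear)

      t_cursor <- t_cursor + dur_s
    }
  }
  list(accel = do.call(rbind, accel_list),
       gps = do.call(rbind, gps_list),
       truth = do.call(rbind, truth_list))
}

#' Simulate a labelled cohort
#'
#' Generates `n_participants` independent multimodal traces over a shared
#' rail network, writing each participant's accelerometer and GPS files
#' in the package dialects plus the network GeoJSON, a truth table and a
#' manifest. Fully reproducible per seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); NULL to skip writing
#'   and return the data in memory.
#' @return List: `network`, `participants` (named list of
#'   [simulate_participant_week()] results), `truth` (bound truth table),
#'   and when `dir` is given, `manifest` (data.frame of written files).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  part_seeds <- sample.int(.Machine$integer.max - 1, config$n_participants)
  network <- simulate_rail_network(
    seed = part_seeds[1] %% 100000L + 7L, extent_km = config$extent_km,
    anchor_lat = config$anchor_lat, anchor_lon = config$anchor_lon)
  ids <- sprintf("p%02d", seq_len(config$n_participants))
  participants <- stats::setNames(lapply(seq_along(ids), function(i) {
    simulate_participant_week(config, ids[i], network,
                              participant_seed = part_seeds[i])
  }), ids)
  truth <- do.call(rbind, lapply(participants, `[[`, "truth"))
  rownames(truth) <- NULL
  out <- list(network = network, participants = participants, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    net_path <- file.path(dir, "rail_network.geojson")
    write_rail_lines(network, net_path)
    files <- c(files, net_path)
    for (id in ids) {
      ap <- file.path(dir, paste0(id, "_accel.csv"))
      gp <- file.path(dir, paste0(id, "_gps.csv"))
      write_raw_accel(participants[[id]]$accel, ap, config$sample_rate_hz)
      write_gps_log(participants[[id]]$gps, gp)
      files <- c(files, ap, gp)
    }
    tp <- file.path(dir, "truth.tsv")
    tt <- truth
    tt$epoch_start <- format(tt$epoch_start, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
    data.table::fwrite(tt, tp, sep = "\t")
    files <- c(files, tp)
    mf <- data.frame(file = basename(files))
    data.table::fwrite(mf, file.path(dir, "manifest.tsv"), sep = "\t")
    out$manifest <- mf
  }
  out
}

#' Attach truth labels to feature rows
#'
#' @param rows feature rows from [participant_features()].
#' @param truth truth table from [simulate_cohort()].
#' @return The rows with a `label` column (mode of the matching epoch).
#' @export
label_rows_from_truth <- function(rows, truth) {
  dt <- data.table::as.data.table(rows)
  key <- paste(truth$participant_id, as.numeric(truth$epoch_start))
  dt[, label := truth$mode[match(
    paste(participant_id, as.numeric(epoch_start)), key)]]
  dt[]
}
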