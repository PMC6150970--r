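# Readers and writers for the three external streams and the internal
# feature table. Dialects are documented stand-ins for ActiLife / Qstarz
# exports: comma-delimited text, optional free-form header block, UTC
# timestamps. Malformed data rows are skipped and counted, never fatal.

.TS_FMT <- "%Y-%m-%d %H:%M:%OS"

.parse_ts <- function(x, utc_offset_s = 0) {
  as.POSIXct(x, format = .TS_FMT, tz = "UTC") - utc_offset_s
}

# first line whose first comma-field parses as a timestamp ends the header
.skip_header_lines <- function(lines) {
  for (i in seq_along(lines)) {
    first <- strsplit(lines[i], ",", fixed = TRUE)[[1]][1]
    if (!is.na(suppressWarnings(.parse_ts(first)))) return(i - 1L)
  }
  length(lines)
}

#' Read a raw accelerometer export
#'
#' Comma-delimited text with an optional free-form header block (device
#' metadata lines, `---` banners or `key: value` pairs); the data part
#' starts at the first line whose first field parses as a timestamp.
#' Columns: timestamp, ax, ay, az (g). Rows that fail numeric parsing are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param path file path.
#' @param sample_rate_hz declared sampling rate (checked against the
#'   observed median interval; >1% disagreement is an error).
#' @param utc_offset_s fixed offset subtracted from file timestamps to
#'   reach UTC (devices that log local time); default 0.
#' @return data.frame `timestamp, ax, ay, az` with attributes
#'   `sample_rate_hz` and `n_skipped`.
#' @export
read_raw_accel <- function(path, sample_rate_hz = 30, utc_offset_s = 0) {
  stopifnot(sample_rate_hz > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  skip <- .skip_header_lines(lines)
  body <- lines[seq_len(length(lines) - skip) + skip]
  # drop a stray column-name line inside the header region edge case
  if (length(body) == 0) stop("no samples")
  parts <- data.table::fread(text = body, header = FALSE, sep = ",",
                             colClasses = "character")
  if (ncol(parts) < 4) stop("dialect error: need timestamp, ax, ay, az")
  ts <- .parse_ts(parts[[1]], utc_offset_s)
  ax <- suppressWarnings(as.numeric(parts[[2]]))
  ay <- suppressWarnings(as.numeric(parts[[3]]))
  az <- suppressWarnings(as.numeric(parts[[4]]))
  ok <- !is.na(ts) & is.finite(ax) & is.finite(ay) & is.finite(az)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("read_raw_accel: skipped %d malformed row(s)", n_skipped))
  }
  ts <- ts[ok]; ax <- ax[ok]; ay <- ay[ok]; az <- az[ok]
  if (length(ts) == 0) stop("no samples")
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) stop("unsorted input")
  if (length(ts) > 2) {
    obs <- stats::median(diff(as.numeric(ts)))
    if (abs(obs - 1 / sample_rate_hz) > 0.01 / sample_rate_hz) {
      stop(sprintf(
        "rate conflict: declared %g Hz, observed interval %.4f s",
        sample_rate_hz, obs))
    }
  }
  out <- data.frame(timestamp = ts, ax = ax, ay = ay, az = az)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a raw accelerometer file in the package dialect
#'
#' @param samples data.frame `timestamp, ax, ay, az`.
#' @param path destination.
#' @param sample_rate_hz rate recorded in the header block.
#' @export
write_raw_accel <- function(samples, path, sample_rate_hz = 30) {
  header <- c(
    "--- raw accelerometer export ---",
    sprintf("sample_rate_hz: %g", sample_rate_hz),
    "units: g",
    "--------------------------------")
  body <- sprintf("%s,%.6f,%.6f,%.6f",
                  format(samples$timestamp, "%Y-%m-%d %H:%M:%OS4",
                         tz = "UTC"),
                  samples$ax, samples$ay, samples$az)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a satellite-info field into SNR values
#'
#' The SAT INFO dialect encodes each tracked satellite as a
#' `SID-ELE-AZI-SNR` token (satellite id, elevation, azimuth, SNR in
#' dB-Hz), tokens joined by `;`. Returns the SNR values in token order;
#' malformed tokens are skipped and counted in attribute `n_malformed`.
#'
#' @param field a single character string (may be empty or NA).
#' @return Numeric vector of SNR values.
#' @export
#' @examples
#' parse_sat_info("#02-48-213-38;#05-67-120-42")  # 38 42
parse_sat_info <- function(field) {
  if (length(field) != 1 || is.na(field) || !nzchar(trimws(field))) {
    out <- numeric(0)
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  tokens <- strsplit(trimws(field), ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  parts <- strsplit(tokens, "-", fixed = TRUE)
  snr <- vapply(parts, function(p) {
    if (length(p) != 4) return(NA_real_)
    suppressWarnings(as.numeric(p[4]))
  }, numeric(1))
  bad <- !is.finite(snr) | snr < 0
  if (any(bad)) {
    warning(sprintf("parse_sat_info: %d malformed token(s)", sum(bad)))
  }
  out <- snr[!bad]
  attr(out, "n_malformed") <- sum(bad)
  out
}

.GPS_COLS <- c("UTC_DATE", "UTC_TIME", "LATITUDE", "N_S", "LONGITUDE",
               "E_W", "SPEED_KMH", "NSAT_USED", "SAT_INFO")

#' Read a GPS track log
#'
#' Comma-delimited Qstarz-style export with a header row naming at least
#' the columns `UTC_DATE, UTC_TIME, LATITUDE, N_S, LONGITUDE, E_W,
#' SPEED_KMH, NSAT_USED, SAT_INFO`; unknown extra columns are ignored.
#' Hemisphere letters are applied as signs (S and W negative) and the
#' SAT INFO field is parsed with [parse_sat_info()].
#'
#' @param path file path.
#' @param utc_offset_s fixed offset subtracted to reach UTC; default 0.
#' @return data.frame with `timestamp` (POSIXct UTC), `lat`, `lon`,
#'   `device_speed` (km/h, NA when blank), `n_sat_used`, and list column
#'   `sat_snr`; attribute `n_skipped` counts dropped rows.
#' @export
read_gps_log <- function(path, utc_offset_s = 0) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character")
  missing_cols <- setdiff(.GPS_COLS, names(dt))
  if (length(missing_cols) > 0) {
    stop("dialect error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- .parse_ts(paste(dt$UTC_DATE, dt$UTC_TIME), utc_offset_s)
  lat <- suppressWarnings(as.numeric(dt$LATITUDE))
  lon <- suppressWarnings(as.numeric(dt$LONGITUDE))
  lat <- ifelse(toupper(trimws(dt$N_S)) == "S", -lat, lat)
  lon <- ifelse(toupper(trimws(dt$E_W)) == "W", -lon, lon)
  speed <- suppressWarnings(as.numeric(dt$SPEED_KMH))
  nsat <- suppressWarnings(as.integer(dt$NSAT_USED))
  ok <- !is.na(ts) & is.finite(lat) & is.finite(lon) &
    abs(lat) <= 90 & abs(lon) <= 180
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("read_gps_log: skipped %d malformed row(s)", n_skipped))
  }
  sat_snr <- lapply(dt$SAT_INFO[ok], function(f)
    suppressWarnings(as.numeric(parse_sat_info(f))))
  out <- data.frame(timestamp = ts[ok], lat = lat[ok], lon = lon[ok],
                    device_speed = speed[ok], n_sat_used = nsat[ok])
  out$sat_snr <- sat_snr
  if (is.unsorted(as.numeric(out$timestamp))) stop("unsorted input")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a GPS log in the package dialect
#'
#' @param fixes data.frame as returned by [read_gps_log()].
#' @param path destination.
#' @export
write_gps_log <- function(fixes, path) {
  sat_info <- vapply(fixes$sat_snr, function(s) {
    if (length(s) == 0) return("")
    paste(sprintf("#%02d-45-180-%g", seq_along(s), s), collapse = ";")
  }, character(1))
  dt <- data.frame(
    UTC_DATE = format(fixes$timestamp, "%Y-%m-%d", tz = "UTC"),
    UTC_TIME = format(fixes$timestamp, "%H:%M:%OS3", tz = "UTC"),
    LATITUDE = sprintf("%.6f", abs(fixes$lat)),
    N_S = ifelse(fixes$lat < 0, "S", "N"),
    LONGITUDE = sprintf("%.6f", abs(fixes$lon)),
    E_W = ifelse(fixes$lon < 0, "W", "E"),
    SPEED_KMH = ifelse(is.na(fixes$device_speed), "",
                       sprintf("%.3f", fixes$device_speed)),
    NSAT_USED = vapply(fixes$sat_snr, length, integer(1)),
    SAT_INFO = sat_info)
  data.table::fwrite(dt, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Read rail lines from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection in WGS84; LineString and
#' MultiLineString features are flattened to polylines, other geometry
#' types are skipped with a warning.
#'
#' @param path GeoJSON file path.
#' @return A [rail_network()].
#' @export
read_rail_lines <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polylines <- list()
  skipped <- 0L
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    coords_to_mat <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(v)
        c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
      colnames(m) <- c("lon", "lat")
      m
    }
    if (identical(geom$type, "LineString")) {
      polylines[[length(polylines) + 1L]] <- coords_to_mat(geom$coordinates)
    } else if (identical(geom$type, "MultiLineString")) {
      for (part in geom$coordinates) {
        polylines[[length(polylines) + 1L]] <- coords_to_mat(part)
      }
    } else {
      skipped <- skipped + 1L
    }
  }
  if (skipped > 0) {
    warning(sprintf("read_rail_lines: skipped %d non-line feature(s)", skipped))
  }
  if (length(polylines) == 0) stop("no rail lines")
  rail_network(polylines)
}

#' Write a rail network as GeoJSON
#'
#' @param network a [rail_network()].
#' @param path destination.
#' @export
write_rail_lines <- function(network, path) {
  feats <- lapply(network$polylines, function(m) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(i)
             c(m[i, "lon"], m[i, "lat"]))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = 9)
  invisible(path)
}

#' Write / read the internal feature table
#'
#' Lossless round-trip of the classifier's feature rows as tab-delimited
#' text with a fixed, documented column order: `participant_id`,
#' `epoch_start` (ISO 8601 UTC), every numeric feature column to 9
#' decimals, the logical flags, and `label` (one of the five mode names
#' or empty). Reading a file whose header contains unknown columns is a
#' schema error.
#'
#' @param rows feature data.frame (as built by [participant_features()]).
#' @param path destination / source.
#' @return `read_feature_table()` returns the feature data.frame.
#' @export
write_feature_table <- function(rows, path) {
  out <- data.table::as.data.table(rows)
  if ("epoch_start" %in% names(out)) {
    out[, epoch_start := format(epoch_start, "%Y-%m-%dT%H:%M:%OS3Z",
                                tz = "UTC")]
  }
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  for (cn in num) {
    v <- out[[cn]]
    out[, (cn) := ifelse(is.na(v), NA_character_, sprintf("%.9f", v))]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  known_prefix <- c("participant_id", "epoch_start", "has_gps", "nonwear",
                    "label")
  known <- names(dt) %in% known_prefix |
    grepl(paste0("^(mad|p10|p90|skew|kurt|fftmean)_[xyz]"), names(dt)) |
    grepl("^(speed_kmh|sum_snr|rail_dist_m|lat|lon|dist_prev_min_m|dist_next_min_m|segment_id)",
          names(dt))
  if (!all(known)) {
    stop("schema error: unknown column(s) ",
         paste(names(dt)[!known], collapse = ", "))
  }
  if ("epoch_start" %in% names(dt) && nrow(dt) > 0) {
    if (inherits(dt$epoch_start, "POSIXct")) {
      dt[, epoch_start := as.POSIXct(as.numeric(epoch_start),
                                     origin = "1970-01-01", tz = "UTC")]
    } else {
      dt[, epoch_start := as.POSIXct(as.character(epoch_start),
                                     format = "%Y-%m-%dT%H:%M:%OSZ",
                                     tz = "UTC")]
    }
  }
  if ("label" %in% names(dt) && nrow(dt) > 0) {
    dt[, label := as.character(label)]
    bad <- !is.na(dt$label) & !(dt$label %in% mode_levels())
    if (any(bad)) stop("schema error: invalid mode label(s)")
  }
  for (flag in c("has_gps", "nonwear")) {
    if (flag %in% names(dt)) dt[, (flag) := as.logical(get(flag))]
  }
  data.frame(dt)
}
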