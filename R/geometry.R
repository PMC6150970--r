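# Distance primitives for the GPS speed fallback and the distance-to-rail
# feature. All distances are metres; coordinates are WGS84 decimal degrees.
# Earth radius fixed at 6,371,000 m throughout.

.EARTH_RADIUS_M <- 6371000

#' Great-circle distance between two points
#'
#' Haversine distance in metres on a sphere of radius 6,371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Numeric vector of distances in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_M)
}

#' Project points to a local planar frame
#'
#' Equirectangular projection anchored at a reference point: x = R *
#' delta-lon * cos(anchor latitude), y = R * delta-lat (radians). Accurate
#' to well under 0.5% of the haversine distance at the <= 10 km scale this
#' package works at; a warning is raised beyond ~100 km from the anchor.
#'
#' @param lat,lon coordinates in decimal degrees (vectorised).
#' @param anchor_lat,anchor_lon anchor of the local frame.
#' @return data.frame with columns `x`, `y` in metres; the anchor maps to
#'   (0, 0).
#' @export
project_local <- function(lat, lon, anchor_lat, anchor_lon) {
  y <- .EARTH_RADIUS_M * (lat - anchor_lat) * pi / 180
  x <- .EARTH_RADIUS_M * (lon - anchor_lon) * pi / 180 *
    cos(anchor_lat * pi / 180)
  if (any(sqrt(x^2 + y^2) > 100e3, na.rm = TRUE)) {
    warning("points beyond ~100 km of the projection anchor; ",
            "planar distances degrade at this scale")
  }
  data.frame(x = x, y = y)
}

#' Distance from a point to a line segment
#'
#' Euclidean distance from `p` to the nearest point of the closed segment
#' (s1, s2) in a planar frame, by clamped orthogonal projection. A
#' degenerate segment (s1 == s2) reduces to point-to-point distance.
#'
#' @param px,py point coordinates, metres (vectorised over points).
#' @param x1,y1,x2,y2 segment end points, metres (vectorised over segments,
#'   recycled against points).
#' @return Numeric vector of distances in metres.
#' @export
point_to_segment_m <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Build a rail network object
#'
#' @param polylines list of numeric matrices, one per polyline, each with
#'   columns `lon`, `lat` (WGS84) and at least two rows.
#' @return An object of class `rail_network`.
#' @export
rail_network <- function(polylines) {
  stopifnot(is.list(polylines))
  polylines <- lapply(polylines, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 2) {
      stop("each polyline needs >= 2 vertices of (lon, lat)")
    }
    if (!all(is.finite(m))) stop("non-finite rail coordinates")
    colnames(m) <- c("lon", "lat")
    m
  })
  structure(list(polylines = polylines), class = "rail_network")
}

#' @export
print.rail_network <- function(x, ...) {
  nv <- sum(vapply(x$polylines, nrow, integer(1)))
  cat(sprintf("<rail_network: %d polyline(s), %d vertices>\n",
              length(x$polylines), nv))
  invisible(x)
}

# Flatten a network to one segment table (start/end lon/lat per segment).
.network_segments <- function(network) {
  segs <- lapply(network$polylines, function(m) {
    n <- nrow(m)
    cbind(lon1 = m[-n, "lon"], lat1 = m[-n, "lat"],
          lon2 = m[-1, "lon"], lat2 = m[-1, "lat"])
  })
  do.call(rbind, segs)
}

#' Minimum distance from points to a rail network
#'
#' For each query point, projects the network into a local planar frame
#' anchored at that point and returns the minimum distance over every
#' segment of every polyline.
#'
#' @param lat,lon query coordinates in decimal degrees (vectorised).
#' @param network a `rail_network`.
#' @return Numeric vector of distances in metres (NA for NA coordinates).
#' @export
distance_to_network_m <- function(lat, lon, network) {
  if (!inherits(network, "rail_network") || length(network$polylines) == 0) {
    stop("no rail lines")
  }
  segs <- .network_segments(network)
  out <- rep(NA_real_, length(lat))
  ok <- which(!is.na(lat) & !is.na(lon))
  for (i in ok) {
    p1 <- project_local(segs[, "lat1"], segs[, "lon1"], lat[i], lon[i])
    p2 <- project_local(segs[, "lat2"], segs[, "lon2"], lat[i], lon[i])
    out[i] <- min(point_to_segment_m(0, 0, p1$x, p1$y, p2$x, p2$y))
  }
  out
}
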