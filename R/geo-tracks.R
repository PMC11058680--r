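# Track representation, projection, denoising and path metrics.

#' Mean Earth radius (IUGG), metres
#' @keywords internal
EARTH_RADIUS_M <- 6371008.8

#' Track processing configuration
#'
#' Bundles the thresholds used throughout track denoising and bout
#' segmentation.
#'
#' @param merge_radius Radius (m) within which successive fixes are merged
#'   into a single location to remove GPS pseudo-movement. Default 30.
#' @param min_bout_separation Minimum beeline separation (m) between a bout's
#'   endpoints for the bout to be retained. Default 50.
#' @param long_distance_threshold Start-to-target distance (m) above which a
#'   day's approach counts as a long-distance movement. Default 1500.
#' @param sampling_interval Nominal fix cadence in minutes. Default 20.
#' @param gps_noise Nominal horizontal GPS accuracy (m). Default 16.5
#'   (midpoint of the 15-18 m handheld-receiver range under canopy).
#' @return An object of class `track_config`.
#' @export
track_config <- function(merge_radius = 30, min_bout_separation = 50,
                         long_distance_threshold = 1500,
                         sampling_interval = 20, gps_noise = 16.5) {
  vals <- c(merge_radius, min_bout_separation, long_distance_threshold,
            sampling_interval, gps_noise)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all track_config values must be strictly positive")
  structure(list(merge_radius = merge_radius,
                 min_bout_separation = min_bout_separation,
                 long_distance_threshold = long_distance_threshold,
                 sampling_interval = sampling_interval,
                 gps_noise = gps_noise),
            class = "track_config")
}

#' Project lat/lon fixes to local planar coordinates
#'
#' Local equirectangular projection about a site reference point:
#' `x = R cos(lat0) dlon`, `y = R dlat` (radians), with R the mean Earth
#' radius. Adequate to within 0.1% of geodesic distance over the few
#' kilometres spanned by a home range near the equator.
#'
#' @param lat,lon Numeric vectors of WGS84 coordinates (degrees).
#' @param origin Numeric `c(lat, lon)` of the projection origin.
#' @return A data.frame with columns `x`, `y` in metres.
#' @export
project_track <- function(lat, lon, origin) {
  stopifnot(length(lat) == length(lon), length(origin) == 2)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates outside valid lat/lon ranges")
  dlat <- lat - origin[1]
  dlon <- lon - origin[2]
  if (any(abs(dlat) > 1 | abs(dlon) > 1))
    stop("fix farther than 1 degree from origin: local projection invalid")
  rad <- pi / 180
  data.frame(x = EARTH_RADIUS_M * cos(origin[1] * rad) * dlon * rad,
             y = EARTH_RADIUS_M * dlat * rad)
}

#' Invert the local projection back to lat/lon
#'
#' @param x,y Planar coordinates (m) from [project_track()].
#' @param origin Numeric `c(lat, lon)` used for the forward projection.
#' @return data.frame with columns `lat`, `lon` (degrees).
#' @export
unproject_track <- function(x, y, origin) {
  rad <- pi / 180
  data.frame(lat = origin[1] + y / EARTH_RADIUS_M / rad,
             lon = origin[2] + x / (EARTH_RADIUS_M * cos(origin[1] * rad)) / rad)
}

#' Haversine great-circle distance (m)
#'
#' Spherical reference distance, used to validate the planar projection.
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Construct a daily track
#'
#' A day's ordered GPS fixes with planar coordinates, plus behavioural scans
#' taken in synchrony with them.
#'
#' @param date A `Date` (or string coercible to one).
#' @param time POSIXct vector of fix timestamps (strictly increasing).
#' @param x,y Planar coordinates (m); see [project_track()].
#' @param lat,lon Optional raw coordinates (degrees).
#' @param origin Projection origin `c(lat, lon)`, or `NULL` for tracks built
#'   directly in planar metres (synthetic data).
#' @param scans Optional data.frame of behavioural scans (see
#'   [behav_scan_table()]).
#' @param context `"unclassified"`, `"swamp"` or `"non-swamp"`.
#' @return An object of class `daily_track`: a list with a `fixes`
#'   data.frame (`time,x,y[,lat,lon]`) and metadata.
#' @export
daily_track <- function(date, time, x, y, lat = NULL, lon = NULL,
                        origin = NULL, scans = NULL,
                        context = "unclassified") {
  date <- as.Date(date)
  if (length(time) < 1) stop("a daily track needs at least one fix")
  stopifnot(length(time) == length(x), length(x) == length(y))
  if (is.unsorted(as.numeric(time), strictly = TRUE))
    stop("fix timestamps must be strictly increasing")
  fixes <- data.frame(time = time, x = x, y = y)
  if (!is.null(lat)) { fixes$lat <- lat; fixes$lon <- lon }
  structure(list(date = date, fixes = fixes, origin = origin,
                 scans = scans, context = context),
            class = "daily_track")
}

#' @export
print.daily_track <- function(x, ...) {
  cat(sprintf("<daily_track> %s: %d fixes, context = %s\n",
              format(x$date), nrow(x$fixes), x$context))
  invisible(x)
}

#' Remove GPS pseudo-movements by anchor-walk merging
#'
#' Keeps the first fix as the anchor; each subsequent fix within
#' `merge_radius` of the current anchor is discarded, and a fix farther away
#' becomes the new anchor. Successive stationary jitter therefore collapses
#' to a single observed location; the pass is deterministic, order-preserving
#' and idempotent.
#'
#' @param fixes data.frame with planar `x`, `y` columns (time-ordered).
#' @param merge_radius Merge radius in metres (default 30).
#' @return The retained subset of `fixes` (row order preserved).
#' @export
denoise_track <- function(fixes, merge_radius = 30) {
  n <- nrow(fixes)
  if (is.null(n) || n == 0) return(fixes)
  keep <- logical(n)
  keep[1] <- TRUE
  ax <- fixes$x[1]; ay <- fixes$y[1]
  for (i in seq_len(n)[-1]) {
    if (sqrt((fixes$x[i] - ax)^2 + (fixes$y[i] - ay)^2) > merge_radius) {
      keep[i] <- TRUE
      ax <- fixes$x[i]; ay <- fixes$y[i]
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Travelled path length of a fix sequence
#'
#' @param fixes data.frame with planar `x`, `y` columns.
#' @return Sum of consecutive Euclidean distances (m).
#' @export
path_length <- function(fixes) {
  if (nrow(fixes) < 2) stop("path_length needs at least 2 fixes")
  sum(sqrt(diff(fixes$x)^2 + diff(fixes$y)^2))
}

#' Straightness index of a fix sequence
#'
#' Beeline distance between the first and last fix divided by the travelled
#' path length; 1 for a perfectly straight monotonic path, near 0 for a
#' closed loop.
#'
#' @param fixes data.frame with planar `x`, `y` columns (>= 2 rows).
#' @return Ratio in `[0, 1]`.
#' @export
straightness <- function(fixes) {
  L <- path_length(fixes)
  if (L <= 0) stop("straightness undefined: zero path length")
  n <- nrow(fixes)
  b <- sqrt((fixes$x[n] - fixes$x[1])^2 + (fixes$y[n] - fixes$y[1])^2)
  b / L
}

#' Read a track CSV into per-day tracks
#'
#' Expects columns `date,time,lat,lon` (ISO-8601 date and HH:MM:SS local
#' clock time, WGS84 decimal degrees); extra columns are ignored. Fixes are
#' projected about `origin` and split by calendar date.
#'
#' @param path CSV file path.
#' @param origin `c(lat, lon)` projection origin.
#' @param tz Time zone of the `time` column. Default `"Etc/GMT-1"` (UTC+1,
#'   no DST).
#' @return A list of [daily_track()] objects, ordered by date.
#' @export
read_track_csv <- function(path, origin, tz = "Etc/GMT-1") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "time", "lat", "lon")
  if (!all(need %in% names(d)))
    stop("track CSV must contain columns: ", paste(need, collapse = ", "))
  tstamp <- as.POSIXct(paste(d$date, d$time), tz = tz)
  pr <- project_track(d$lat, d$lon, origin)
  split_idx <- split(seq_len(nrow(d)), d$date)
  lapply(split_idx, function(i) {
    o <- i[order(tstamp[i])]
    daily_track(date = d$date[o[1]], time = tstamp[o],
                x = pr$x[o], y = pr$y[o],
                lat = d$lat[o], lon = d$lon[o], origin = origin)
  })
}
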