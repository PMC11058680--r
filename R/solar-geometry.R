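# Solar position (NOAA simplified ephemeris) and the cos(elevation)
# covariate attached to movement bouts.

#' Solar position at an instant
#'
#' NOAA's simplified solar ephemeris (Meeus-based): solar declination and
#' equation of time from the Julian century, then local hour angle to
#' elevation and azimuth. Accuracy is a few hundredths of a degree for
#' declination and well under 0.5 degrees in elevation over 1900-2100;
#' atmospheric refraction is ignored (it only matters within ~0.6 degrees of
#' the horizon and is irrelevant for a cos-elevation covariate).
#'
#' @param time POSIXct vector (any time zone; converted to UTC internally).
#' @param lat,lon Observer coordinates, degrees (north/east positive).
#' @return data.frame with `elevation` (degrees above horizon, negative at
#'   night), `azimuth` (degrees clockwise from north, `[0, 360)`) and
#'   `cos_elevation`.
#' @export
sun_position <- function(time, lat, lon) {
  stopifnot(inherits(time, "POSIXct"))
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  if (any(yr < 1900 | yr > 2100))
    stop("sun_position valid for 1900-2100 only")
  rad <- pi / 180
  # Julian day from Unix epoch (1970-01-01 00:00 UTC = JD 2440587.5)
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525       # Julian centuries since J2000.0

  L0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  M  <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ec <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  C  <- sin(M * rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
        sin(2 * M * rad) * (0.019993 - 0.000101 * t) +
        sin(3 * M * rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * rad)

  e0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  obliq <- e0 + 0.00256 * cos(omega * rad)

  decl <- asin(sin(obliq * rad) * sin(app_long * rad)) / rad

  y <- tan(obliq / 2 * rad)^2
  eqtime <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * ec * sin(M * rad) +
                       4 * ec * y * sin(M * rad) * cos(2 * L0 * rad) -
                       0.5 * y^2 * sin(4 * L0 * rad) -
                       1.25 * ec^2 * sin(2 * M * rad))   # minutes

  mins_utc <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440           # true solar time
  ha <- tst / 4 - 180                                    # hour angle, deg
  ha[ha < -180] <- ha[ha < -180] + 360

  cos_zen <- sin(lat * rad) * sin(decl * rad) +
             cos(lat * rad) * cos(decl * rad) * cos(ha * rad)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen) / rad
  elev <- 90 - zen

  sin_zen <- sin(zen * rad)
  az_arg <- (sin(lat * rad) * cos_zen - sin(decl * rad)) /
            (cos(lat * rad) * sin_zen)
  az_arg <- pmin(1, pmax(-1, az_arg))
  az <- acos(az_arg) / rad
  azimuth <- ifelse(ha > 0, (az + 180) %% 360, (540 - az) %% 360)
  # degenerate zenith/nadir: azimuth undefined, report 0
  azimuth[sin_zen < 1e-12] <- 0

  data.frame(elevation = elev, azimuth = azimuth,
             cos_elevation = cos(elev * rad))
}

#' Sun-elevation covariate for a movement bout
#'
#' Evaluates `cos(elevation)` at the bout's mid-time
#' (`start + (end - start)/2`), the proxy used for how easily the sun's
#' azimuth can be read off (hardest when the sun is near the zenith).
#'
#' @param bout A `movement_bout` (or any list with POSIXct `start_time` and
#'   `end_time`).
#' @param site `c(lat, lon)` of the study site, degrees.
#' @return `cos(elevation)` at the bout mid-time (scalar).
#' @export
bout_sun_covariate <- function(bout, site) {
  if (is.null(bout$start_time) || is.null(bout$end_time) ||
      any(is.na(c(bout$start_time, bout$end_time))))
    stop("bout is missing start/end timestamps")
  mid <- bout$start_time + as.numeric(difftime(bout$end_time,
                                               bout$start_time,
                                               units = "secs")) / 2
  sun_position(mid, site[1], site[2])$cos_elevation
}
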