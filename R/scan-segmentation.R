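# Behavioural scans, feeding-event detection, day classification and
# segmentation of daily tracks into movement bouts.

#' Build a behavioural scan table
#'
#' One row per (scan, food species/type) combination, mirroring the field
#' protocol: group scans every 20 min recording how many (sub)adults are
#' visible and what each is feeding on, plus weather (0 blue sky /
#' 1 overcast) and canopy/understorey openness (0 closed .. 3 open).
#'
#' @param time POSIXct scan timestamps.
#' @param n_adults_visible Integer count of visible (sub)adults per row.
#' @param species,food_type Character; `NA` for rows with no feeding.
#' @param n_feeding Count of (sub)adults feeding on that species/type.
#' @param weather 0/1; `canopy`,`understorey` ordinal 0-3;
#'   `vegetation` free label.
#' @param canopy,understorey,vegetation See above.
#' @return data.frame of class `behav_scan_table`, validated.
#' @export
behav_scan_table <- function(time, n_adults_visible, species, food_type,
                             n_feeding, weather, canopy, understorey,
                             vegetation = NA_character_) {
  d <- data.frame(time = time, n_adults_visible = n_adults_visible,
                  species = species, food_type = food_type,
                  n_feeding = n_feeding, weather = weather,
                  canopy = canopy, understorey = understorey,
                  vegetation = vegetation, stringsAsFactors = FALSE)
  validate_scan_table(d)
  class(d) <- c("behav_scan_table", class(d))
  d
}

#' @keywords internal
validate_scan_table <- function(d) {
  if (!all(d$weather %in% c(0, 1)))
    stop("weather must be 0 (blue sky) or 1 (overcast)")
  if (any(d$canopy < 0 | d$canopy > 3) || any(d$understorey < 0 | d$understorey > 3))
    stop("openness scores must lie in [0, 3]")
  tot <- tapply(ifelse(is.na(d$n_feeding), 0, d$n_feeding),
                format(d$time, "%Y-%m-%d %H:%M:%S"), sum)
  nv <- tapply(d$n_adults_visible, format(d$time, "%Y-%m-%d %H:%M:%S"), max)
  if (any(tot > nv))
    stop("total feeding count exceeds visible (sub)adults in a scan")
  invisible(d)
}

#' Detect a group feeding event in one scan
#'
#' A feeding event requires at least three visible (sub)adults with at least
#' half of them (ceiling of n/2) feeding on the same food species; this
#' excludes opportunistic snacking by single individuals.
#'
#' @param scan data.frame rows of one scan (same timestamp): columns
#'   `n_adults_visible`, `species`, `food_type`, `n_feeding`.
#' @return `NULL` if no event, else a list with `species`, `food_type`,
#'   `n_feeding`, `n_visible`.
#' @export
detect_feeding_event <- function(scan) {
  nv <- max(scan$n_adults_visible)
  if (is.na(nv) || nv < 3) return(NULL)
  feed <- scan[!is.na(scan$species) & !is.na(scan$n_feeding) & scan$n_feeding > 0, ]
  if (nrow(feed) == 0) return(NULL)
  per_sp <- tapply(feed$n_feeding, feed$species, sum)
  top <- which.max(per_sp)
  if (per_sp[top] < ceiling(nv / 2)) return(NULL)
  sp <- names(per_sp)[top]
  ft <- feed$food_type[feed$species == sp][1]
  list(species = sp, food_type = ft,
       n_feeding = unname(per_sp[top]), n_visible = nv)
}

#' Locate feeding events along a daily track
#'
#' Applies [detect_feeding_event()] to each scan of the day and attaches the
#' synchronous fix (nearest in time) as the feeding-site location.
#'
#' @param track A [daily_track()] with a `scans` table.
#' @return data.frame `time, species, food_type, x, y` (possibly 0 rows).
#' @export
feeding_events <- function(track) {
  empty <- data.frame(time = as.POSIXct(character()), species = character(),
                      food_type = character(), x = numeric(), y = numeric())
  sc <- track$scans
  if (is.null(sc) || nrow(sc) == 0) return(empty)
  out <- list()
  for (tt in unique(as.numeric(sc$time))) {
    rows <- sc[as.numeric(sc$time) == tt, ]
    ev <- detect_feeding_event(rows)
    if (is.null(ev)) next
    i <- which.min(abs(as.numeric(track$fixes$time) - tt))
    out[[length(out) + 1]] <- data.frame(
      time = rows$time[1], species = ev$species, food_type = ev$food_type,
      x = track$fixes$x[i], y = track$fixes$y[i])
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$time), ]
}

#' @keywords internal
new_bout <- function(fixes, mode, context = "unclassified") {
  n <- nrow(fixes)
  b <- sqrt((fixes$x[n] - fixes$x[1])^2 + (fixes$y[n] - fixes$y[1])^2)
  L <- path_length(fixes)
  st <- fixes$time[1]; en <- fixes$time[n]
  structure(list(fixes = fixes, start_time = st, end_time = en,
                 mid_time = st + as.numeric(difftime(en, st, units = "secs")) / 2,
                 beeline = b, path_length = L, straightness = b / L,
                 mode = mode, context = context,
                 weather = NA_real_, canopy = NA_real_,
                 understorey = NA_real_, cos_elevation = NA_real_),
            class = "movement_bout")
}

#' @export
print.movement_bout <- function(x, ...) {
  cat(sprintf("<movement_bout %s> %d fixes, beeline %.0f m, s = %.3f\n",
              x$mode, nrow(x$fixes), x$beeline, x$straightness))
  invisible(x)
}

#' Segment a foraging day into bouts between successive feeding sites
#'
#' One candidate bout per pair of consecutive feeding events; a bout is kept
#' only if the two feeding sites are more than `min_bout_separation` apart
#' (to exclude sensory-driven moves) and at least one fix falls strictly
#' between them in time (a two-point straightness is meaningless). Bout
#' fixes are all fixes with timestamps in `[t_start, t_end]`.
#'
#' @param track A classified [daily_track()] (non-swamp day).
#' @param events Feeding events from [feeding_events()] (time-ordered).
#' @param cfg A [track_config()].
#' @return List of `movement_bout` objects (possibly empty).
#' @export
segment_bouts_foraging <- function(track, events, cfg = track_config()) {
  bouts <- list()
  if (is.null(events) || nrow(events) < 2) return(bouts)
  fx <- track$fixes
  for (k in seq_len(nrow(events) - 1)) {
    a <- events[k, ]; b <- events[k + 1, ]
    sep <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
    if (sep <= cfg$min_bout_separation) next
    inside <- fx$time > a$time & fx$time < b$time
    if (!any(inside)) next
    sel <- fx[fx$time >= a$time & fx$time <= b$time, , drop = FALSE]
    if (nrow(sel) < 3) next
    bouts[[length(bouts) + 1]] <- new_bout(sel, "foraging", track$context)
  }
  bouts
}

#' Segment a directed long-distance movement into extended fix triples
#'
#' Greedy forward partition of the ordered fixes (day start to target
#' entry): open a window of three consecutive fixes and, while the first and
#' last fixes of the window are not more than `min_bout_separation` apart,
#' extend it with the next fix. Windows do not overlap; trailing fixes that
#' cannot form a valid bout are dropped.
#'
#' @param track A [daily_track()] (fixes already truncated at target entry).
#' @param cfg A [track_config()].
#' @return List of `movement_bout` objects.
#' @export
segment_bouts_directed <- function(track, cfg = track_config()) {
  fx <- track$fixes
  n <- nrow(fx)
  bouts <- list()
  i <- 1
  while (i + 2 <= n) {
    j <- i + 2
    sep <- function(a, b) sqrt((fx$x[b] - fx$x[a])^2 + (fx$y[b] - fx$y[a])^2)
    while (sep(i, j) <= cfg$min_bout_separation && j < n) j <- j + 1
    if (sep(i, j) <= cfg$min_bout_separation) break  # trailing remainder
    bouts[[length(bouts) + 1]] <-
      new_bout(fx[i:j, , drop = FALSE], "directed", track$context)
    i <- j + 1
  }
  bouts
}

#' Classify a day as swamp or non-swamp
#'
#' A swamp day has at least one fix inside the swamp polygon; the entry fix
#' is the first such fix and the start distance is the planar distance from
#' the day's first fix to the entry fix. A start distance above
#' `long_distance_threshold` marks a long-distance approach.
#'
#' @param track A [daily_track()].
#' @param swamp_polygon Two-column matrix/data.frame of planar vertex
#'   coordinates (closed or open ring), or `NULL` for sites without a
#'   mapped target.
#' @param cfg A [track_config()].
#' @return List: `context` ("swamp"/"non-swamp"), `entry_index`, `entry_fix`
#'   (row or `NULL`), `start_distance`, `long_distance`.
#' @export
classify_day <- function(track, swamp_polygon, cfg = track_config()) {
  if (is.null(swamp_polygon)) {
    track_set <- list(context = "non-swamp", entry_index = NA_integer_,
                      entry_fix = NULL, start_distance = NA_real_,
                      long_distance = FALSE)
    return(track_set)
  }
  poly <- as.matrix(swamp_polygon)
  if (!is.numeric(poly) || ncol(poly) != 2 || nrow(poly) < 3)
    stop("invalid swamp polygon: need >= 3 numeric x/y vertices")
  fx <- track$fixes
  inside <- mgcv::in.out(poly, cbind(fx$x, fx$y))
  if (!any(inside)) {
    return(list(context = "non-swamp", entry_index = NA_integer_,
                entry_fix = NULL, start_distance = NA_real_,
                long_distance = FALSE))
  }
  k <- which(inside)[1]
  d0 <- sqrt((fx$x[k] - fx$x[1])^2 + (fx$y[k] - fx$y[1])^2)
  list(context = "swamp", entry_index = k, entry_fix = fx[k, ],
       start_distance = d0,
       long_distance = d0 > cfg$long_distance_threshold)
}

#' Attach scan covariates and solar covariate to bouts
#'
#' Each bout receives the weather and openness scores of the scan nearest in
#' time to its mid-time (ties broken toward the earlier scan) and, when
#' `site` is given, `cos(sun elevation)` at the mid-time.
#'
#' @param bouts List of `movement_bout`s.
#' @param scans Scan table with `time`, `weather`, `canopy`, `understorey`.
#' @param site Optional `c(lat, lon)` for the solar covariate.
#' @return The bout list with covariates filled in.
#' @export
attach_bout_covariates <- function(bouts, scans, site = NULL) {
  if (length(bouts) == 0) return(bouts)
  st <- as.numeric(scans$time)
  for (k in seq_along(bouts)) {
    b <- bouts[[k]]
    dt <- abs(st - as.numeric(b$mid_time))
    i <- which(dt == min(dt))[1]        # earliest on ties (stable order)
    b$weather <- scans$weather[i]
    b$canopy <- scans$canopy[i]
    b$understorey <- scans$understorey[i]
    if (!is.null(site)) b$cos_elevation <- bout_sun_covariate(b, site)
    bouts[[k]] <- b
  }
  bouts
}

#' Read a scan CSV
#'
#' Columns `date,time,n_adults_visible,species,food_type,n_feeding,weather,
#' canopy,understorey,vegetation`, one row per species per scan; empty
#' species fields mark scans without feeding.
#'
#' @param path CSV file path.
#' @param tz Time zone of the clock times (default UTC+1, no DST).
#' @return A `behav_scan_table`.
#' @export
read_scan_csv <- function(path, tz = "Etc/GMT-1") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(species = "character",
                                         food_type = "character"))
  d$species[d$species == ""] <- NA_character_
  d$food_type[d$food_type == ""] <- NA_character_
  behav_scan_table(time = as.POSIXct(paste(d$date, d$time), tz = tz),
                   n_adults_visible = d$n_adults_visible,
                   species = d$species, food_type = d$food_type,
                   n_feeding = d$n_feeding, weather = d$weather,
                   canopy = d$canopy, understorey = d$understorey,
                   vegetation = d$vegetation)
}

#' Read a swamp polygon from GeoJSON and project it
#'
#' Accepts a GeoJSON `Polygon` geometry (or a Feature/FeatureCollection
#' whose first geometry is a Polygon) in WGS84 and returns the outer ring in
#' planar metres about `origin`.
#'
#' @param path GeoJSON file path.
#' @param origin `c(lat, lon)` projection origin.
#' @return Two-column matrix of planar vertex coordinates.
#' @export
read_swamp_geojson <- function(path, origin) {
  g <- jsonlite::read_json(path)
  geom <- g
  if (!is.null(g$type) && g$type == "FeatureCollection") geom <- g$features[[1]]$geometry
  if (!is.null(geom$type) && geom$type == "Feature") geom <- geom$geometry
  if (is.null(geom$type) || geom$type != "Polygon")
    stop("expected a GeoJSON Polygon geometry")
  ring <- geom$coordinates[[1]]
  lon <- vapply(ring, function(p) p[[1]], numeric(1))
  lat <- vapply(ring, function(p) p[[2]], numeric(1))
  pr <- project_track(lat, lon, origin)
  as.matrix(pr)
}
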