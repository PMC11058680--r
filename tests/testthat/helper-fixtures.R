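# Shared in-code fixtures for the suite.

# A planar daily track from bare coordinates, timestamps every 20 min.
toy_track <- function(x, y, date = "2013-03-01", context = "unclassified") {
  times <- as.POSIXct(paste(date, "08:00:00"), tz = "Etc/GMT-1") +
    seq_along(x) * 1200
  daily_track(date = date, time = times, x = x, y = y, context = context)
}

# One-scan table with a configurable feeding split.
toy_scan <- function(n_visible, feeding = list(), time = NULL,
                     weather = 0, canopy = 1.5, understorey = 1.5) {
  if (is.null(time))
    time <- as.POSIXct("2013-03-01 09:00:00", tz = "Etc/GMT-1")
  if (length(feeding) == 0)
    return(data.frame(time = time, n_adults_visible = n_visible,
                      species = NA_character_, food_type = NA_character_,
                      n_feeding = NA_real_, weather = weather,
                      canopy = canopy, understorey = understorey))
  data.frame(time = time, n_adults_visible = n_visible,
             species = names(feeding),
             food_type = "stems",
             n_feeding = unlist(feeding, use.names = FALSE),
             weather = weather, canopy = canopy, understorey = understorey)
}

# Independent haversine oracle (inline, spherical closed form).
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * R * asin(sqrt(a))
}
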