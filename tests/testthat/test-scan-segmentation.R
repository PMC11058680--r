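test_that("detect_feeding_event applies the half-of-visible rule", {
  # 4 visible, 2 on one species: threshold ceiling(4/2) = 2 met exactly
  ev <- detect_feeding_event(toy_scan(4, list(A = 2)))
  expect_equal(ev$species, "A")

  # fewer than 3 visible: never an event
  expect_null(detect_feeding_event(toy_scan(2, list(A = 2))))

  # 6 visible, 3 feeding but split over 3 species: no modal majority
  expect_null(detect_feeding_event(toy_scan(6, list(A = 1, B = 1, C = 1))))

  # odd n uses the ceiling: 5 visible needs 3
  expect_null(detect_feeding_event(toy_scan(5, list(A = 2))))
  expect_equal(detect_feeding_event(toy_scan(5, list(A = 3)))$species, "A")

  # monotone: adding one more feeder on the modal species keeps the event
  set.seed(31)
  for (k in 1:25) {
    nv <- sample(3:9, 1)
    nf <- sample(0:(nv - 1), 1)
    base <- detect_feeding_event(toy_scan(nv, list(A = nf)))
    more <- detect_feeding_event(toy_scan(nv, list(A = nf + 1)))
    if (!is.null(base)) expect_false(is.null(more))
  }
})

test_that("foraging segmentation keeps only well-separated 3+ fix bouts", {
  tr <- toy_track(c(0, 100, 200), c(0, 20, 0))
  ev <- data.frame(time = tr$fixes$time[c(1, 3)],
                   species = "A", food_type = "stems",
                   x = c(0, 200), y = c(0, 0))
  bouts <- segment_bouts_foraging(tr, ev)
  expect_length(bouts, 1)
  expect_equal(nrow(bouts[[1]]$fixes), 3)
  # 200 beeline over two 101.98-m legs
  expect_equal(bouts[[1]]$straightness, 200 / (2 * sqrt(100^2 + 20^2)),
               tolerance = 1e-12)

  # feeding sites only 40 m apart: excluded
  ev40 <- data.frame(time = tr$fixes$time[c(1, 3)], species = "A",
                     food_type = "stems", x = c(0, 40), y = c(0, 0))
  expect_length(segment_bouts_foraging(tr, ev40), 0)

  # 200 m apart but no intermediate fix: excluded
  tr2 <- toy_track(c(0, 200), c(0, 0))
  ev2 <- data.frame(time = tr2$fixes$time, species = "A",
                    food_type = "stems", x = c(0, 200), y = c(0, 0))
  expect_length(segment_bouts_foraging(tr2, ev2), 0)

  # fewer than two events: nothing to segment
  expect_length(segment_bouts_foraging(tr, ev[1, ]), 0)
})

test_that("directed segmentation partitions greedily without overlap", {
  # 6 collinear fixes 100 m apart -> two 3-fix bouts
  tr <- toy_track(seq(0, 500, by = 100), rep(0, 6))
  bouts <- segment_bouts_directed(tr)
  expect_length(bouts, 2)
  expect_equal(vapply(bouts, function(b) nrow(b$fixes), numeric(1)), c(3, 3))

  # 12 fixes 10 m apart: window extends to 7 fixes (60 m); the 5-fix
  # remainder can only span 40 m and is dropped
  tr2 <- toy_track(seq(0, 110, by = 10), rep(0, 12))
  bouts2 <- segment_bouts_directed(tr2)
  expect_length(bouts2, 1)
  expect_equal(nrow(bouts2[[1]]$fixes), 7)
  expect_equal(bouts2[[1]]$beeline, 60)

  # below the 3-fix minimum
  expect_length(segment_bouts_directed(toy_track(c(0, 100), c(0, 0))), 0)

  # property: every bout satisfies beeline > 50 and >= 3 fixes; bouts
  # partition a prefix of the fix sequence without overlap
  set.seed(13)
  for (k in 1:10) {
    n <- sample(10:40, 1)
    tr3 <- toy_track(cumsum(runif(n, 5, 120)), cumsum(rnorm(n, 0, 30)))
    bts <- segment_bouts_directed(tr3)
    if (length(bts) == 0) next
    expect_true(all(vapply(bts, function(b) b$beeline > 50, logical(1))))
    expect_true(all(vapply(bts, function(b) nrow(b$fixes) >= 3, logical(1))))
    times <- lapply(bts, function(b) as.numeric(b$fixes$time))
    for (i in seq_len(length(bts) - 1))
      expect_lt(max(times[[i]]), min(times[[i + 1]]))
  }
})

test_that("classify_day finds swamp entry and long-distance starts", {
  poly <- cbind(c(1900, 2100, 2100, 1900), c(-100, -100, 100, 100))

  # never enters
  out <- classify_day(toy_track(c(0, 100, 200), c(0, 0, 0)), poly)
  expect_equal(out$context, "non-swamp")
  expect_false(out$long_distance)

  # starts inside: start distance 0, not long-distance
  inpoly <- classify_day(toy_track(c(2000, 2050, 2010), c(0, 10, -10)), poly)
  expect_equal(inpoly$context, "swamp")
  expect_equal(inpoly$entry_index, 1)
  expect_equal(inpoly$start_distance, 0)
  expect_false(inpoly$long_distance)

  # approaches from 2000 m away and enters
  tr <- toy_track(seq(0, 2000, by = 250), rep(0, 9))
  cl <- classify_day(tr, poly)
  expect_equal(cl$context, "swamp")
  expect_equal(cl$entry_index, 9)
  expect_equal(cl$start_distance, 2000)
  expect_true(cl$long_distance)

  expect_error(classify_day(tr, cbind(1, 1)), "polygon")
})

test_that("generator swamp days classify with ~known start distance", {
  sim <- sim_config()
  for (seed in c(101, 202, 303)) {
    tr <- generate_brw_day(sim, start_distance = 2000, seed = seed)
    if (!isTRUE(attr(tr, "reached"))) next
    cl <- classify_day(tr, sim$swamp_polygon)
    expect_equal(cl$context, "swamp")
    # start is 2000 m from the polygon centroid; entry is at the boundary,
    # so the start distance is below 2000 plus noise/overshoot slack
    expect_gt(cl$start_distance, 1500)
    expect_lt(cl$start_distance, 2200)
  }
})

test_that("bout covariates come from the scan nearest the mid-time", {
  tr <- toy_track(seq(0, 500, by = 100), rep(0, 6))
  b <- segment_bouts_directed(tr)
  scan_times <- tr$fixes$time
  scans <- data.frame(time = scan_times, weather = c(0, 1, 0, 1, 0, 1),
                      canopy = 1:6 / 2, understorey = 6:1 / 2)
  bb <- attach_bout_covariates(b, scans)
  # bout 1 covers fixes 1-3, mid-time = fix 2's time exactly
  expect_equal(bb[[1]]$weather, 1)
  expect_equal(bb[[1]]$canopy, 1.0)
  # solar covariate attaches when a site is supplied
  bb2 <- attach_bout_covariates(b, scans, site = c(2.3667, 16.2667))
  expect_true(all(is.finite(vapply(bb2, `[[`, numeric(1), "cos_elevation"))))
})

test_that("scan CSV reader validates and round-trips", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "date,time,n_adults_visible,species,food_type,n_feeding,weather,canopy,understorey,vegetation",
    "2013-03-01,09:00:00,5,Hydrocharis,roots,3,0,1.5,2,swamp",
    "2013-03-01,09:00:00,5,Culcasia,leaves,1,0,1.5,2,swamp",
    "2013-03-01,09:20:00,4,,,,1,1,1,mixed"), tmp)
  sc <- read_scan_csv(tmp)
  expect_equal(nrow(sc), 3)
  ev <- detect_feeding_event(sc[sc$time == sc$time[1], ])
  expect_equal(ev$species, "Hydrocharis")
  unlink(tmp)

  expect_error(behav_scan_table(
    time = as.POSIXct("2013-03-01 09:00:00", tz = "Etc/GMT-1"),
    n_adults_visible = 2, species = "A", food_type = "stems",
    n_feeding = 3, weather = 0, canopy = 1, understorey = 1),
    "exceeds")
})

test_that("GeoJSON polygon reader projects the outer ring", {
  tmp <- tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"Feature","geometry":{"type":"Polygon","coordinates":',
    '[[[16.28,2.38],[16.30,2.38],[16.30,2.40],[16.28,2.40],[16.28,2.38]]]}}'),
    tmp)
  poly <- read_swamp_geojson(tmp, c(2.3667, 16.2667))
  expect_equal(ncol(poly), 2)
  expect_equal(nrow(poly), 5)
  expect_true(all(poly[, 1] > 0))  # east of the site
  unlink(tmp)
})
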