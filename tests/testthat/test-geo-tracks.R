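test_that("projection matches the haversine oracle and round-trips", {
  origin <- c(2.3667, 16.2667)
  # identity at the origin
  p0 <- project_track(origin[1], origin[2], origin)
  expect_equal(unlist(p0), c(x = 0, y = 0))

  # 0.01 degree due north ~ 1111.95 m, against the spherical oracle
  p1 <- project_track(origin[1] + 0.01, origin[2], origin)
  expect_equal(p1$x, 0)
  expect_equal(p1$y,
               haversine_oracle(origin[1], origin[2], origin[1] + 0.01, origin[2]),
               tolerance = 1e-6)
  expect_equal(p1$y, 1111.95, tolerance = 1e-4)

  # two points ~2 km apart near 2.37 N: planar distance within 2 m of oracle
  a <- c(2.360, 16.260); b <- c(2.372, 16.274)
  pr <- project_track(c(a[1], b[1]), c(a[2], b[2]), origin)
  planar <- sqrt(diff(pr$x)^2 + diff(pr$y)^2)
  geo <- haversine_oracle(a[1], a[2], b[1], b[2])
  expect_gt(geo, 1500)
  expect_lt(abs(planar - geo), 2)

  # round-trip recovers lat/lon within 1e-9 degrees
  set.seed(5)
  lat <- origin[1] + runif(50, -0.5, 0.5)
  lon <- origin[2] + runif(50, -0.5, 0.5)
  pr <- project_track(lat, lon, origin)
  back <- unproject_track(pr$x, pr$y, origin)
  expect_lt(max(abs(back$lat - lat)), 1e-9)
  expect_lt(max(abs(back$lon - lon)), 1e-9)

  expect_error(project_track(origin[1] + 1.5, origin[2], origin), "1 degree")
})

test_that("denoise_track applies the anchor-walk rule", {
  fx <- data.frame(x = c(0, 10, 20, 50), y = 0)
  expect_equal(denoise_track(fx, 30)$x, c(0, 50))

  # all identical -> single fix
  same <- data.frame(x = rep(3, 7), y = rep(4, 7))
  expect_equal(nrow(denoise_track(same, 30)), 1)

  # fixes spaced beyond the radius are untouched
  far <- data.frame(x = seq(0, 400, by = 40), y = 0)
  expect_equal(denoise_track(far, 30), far)

  # idempotence on jittered random walks
  set.seed(42)
  for (k in 1:5) {
    w <- data.frame(x = cumsum(rnorm(200, 0, 20)), y = cumsum(rnorm(200, 0, 20)))
    d1 <- denoise_track(w, 30)
    expect_identical(denoise_track(d1, 30), d1)
    # consecutive retained fixes separated by more than the radius
    expect_true(all(sqrt(diff(d1$x)^2 + diff(d1$y)^2) > 30))
  }

  expect_equal(nrow(denoise_track(data.frame(x = numeric(), y = numeric()))), 0)
})

test_that("path_length and straightness behave analytically", {
  expect_equal(path_length(data.frame(x = c(0, 3), y = c(0, 4))), 5)
  L <- data.frame(x = c(0, 100, 100), y = c(0, 0, 100))
  expect_equal(path_length(L), 200)
  expect_equal(straightness(L), sqrt(2) * 100 / 200)

  # collinear path is perfectly straight; closed loop has straightness 0
  expect_equal(straightness(data.frame(x = 0:5 * 10, y = 0:5 * 7)), 1)
  loop <- data.frame(x = c(0, 100, 100, 0, 0), y = c(0, 0, 100, 100, 0))
  expect_equal(straightness(loop), 0)

  expect_error(path_length(data.frame(x = 1, y = 1)), "at least 2")
  expect_error(straightness(data.frame(x = c(1, 1), y = c(2, 2))), "zero path")
})

test_that("straightness is bounded and rigid-motion invariant", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(3:50, 1)
    fx <- data.frame(x = cumsum(rnorm(n, 0, 50)), y = cumsum(rnorm(n, 0, 50)))
    s <- straightness(fx)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_gte(path_length(fx), sqrt(diff(range(fx$x[c(1, n)]))^2 +
                                     diff(fx$y[c(1, n)])^2))
    th <- runif(1, 0, 2 * pi); dx <- runif(2, -500, 500)
    rot <- data.frame(x = cos(th) * fx$x - sin(th) * fx$y + dx[1],
                      y = sin(th) * fx$x + cos(th) * fx$y + dx[2])
    expect_equal(straightness(rot), s, tolerance = 1e-10)
    expect_equal(path_length(rot), path_length(fx), tolerance = 1e-8)
  }
})

test_that("path_length is additive over concatenated sub-paths", {
  set.seed(9)
  fx <- data.frame(x = cumsum(rnorm(30, 0, 40)), y = cumsum(rnorm(30, 0, 40)))
  k <- 12
  expect_equal(path_length(fx),
               path_length(fx[1:k, ]) + path_length(fx[k:30, ]))
})

test_that("track CSV reader round-trips and tolerates extra columns", {
  origin <- c(2.3667, 16.2667)
  sim <- sim_config()
  tr <- generate_crw_day(sim, seed = 21)
  ll <- unproject_track(tr$fixes$x, tr$fixes$y, origin)
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(date = format(tr$date),
                       time = format(tr$fixes$time, "%H:%M:%S"),
                       lat = ll$lat, lon = ll$lon,
                       observer = "A"),   # extra column must be tolerated
            tmp, row.names = FALSE)
  days <- read_track_csv(tmp, origin)
  expect_length(days, 1)
  expect_equal(days[[1]]$fixes$x, tr$fixes$x, tolerance = 1e-6)
  expect_equal(days[[1]]$fixes$y, tr$fixes$y, tolerance = 1e-6)
  unlink(tmp)
})

test_that("daily_track validates its invariants", {
  tt <- as.POSIXct("2013-03-01 08:00:00", tz = "Etc/GMT-1") + c(0, 0, 60)
  expect_error(daily_track("2013-03-01", tt, 1:3, 1:3), "strictly increasing")
  expect_error(track_config(merge_radius = -1), "positive")
})
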