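# Synthetic tracks, scans and regression datasets with known ground truth.
#
# The generators stand in for access-restricted field data: 20-min GPS fixes
# with handheld-receiver noise, tortuous correlated-random-walk foraging
# days interleaved with behavioural scans, rare straight biased-random-walk
# days towards a distant swamp target, and covariate distributions matching
# the reported field moments.

#' Synthetic-data configuration
#'
#' Defaults encode the study system: dawn-to-dusk days sampled every
#' 20 min, per-axis GPS noise SD 8 m (mean radial error ~10 m, consistent
#' with a 15-18 m handheld accuracy under canopy), tortuous foraging days
#' (wrapped-normal CRW, rho = 0.8, mean step 60 m so daily travel is about
#' 1 km) and directed swamp approaches (von Mises BRW, kappa = 8, mean step
#' 150 m: swamp journeys cover three times the usual daily distance with
#' few stops). Scan covariates follow the reported field moments: canopy
#' openness ~ Normal(1.42, 0.39) and understorey ~ Normal(1.52, 0.43), both
#' truncated to [0, 3]; weather is Bernoulli(0.5); one scan in 0.3 carries
#' a group feeding event.
#'
#' @param n_days Number of days for multi-day simulations.
#' @param fraction_swamp_days Fraction of days that are swamp approaches.
#' @param step_mean_crw,step_mean_brw Mean step length (m per 20-min step).
#' @param crw_rho Turning-angle concentration of the CRW (`[0, 1)`).
#' @param brw_kappa von Mises concentration of BRW headings about the
#'   bearing to target.
#' @param gps_noise_sd Per-axis Gaussian GPS noise SD (m).
#' @param site `c(lat, lon)` of the site (projection origin).
#' @param swamp_polygon Two-column matrix of planar vertices; default a
#'   500 m square centred 3.2 km northeast of the site.
#' @param weather_p P(overcast) per scan.
#' @param canopy_mean,canopy_sd,understorey_mean,understorey_sd Openness
#'   score distributions (truncated normal on `[0, 3]`).
#' @param feeding_rate P(a scan carries a feeding event).
#' @param dist_mean,dist_sd Mean and SD (m) of raw bout travelled distance;
#'   the regression generator uses a moment-matched log-normal.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_days = 200, fraction_swamp_days = 8 / 200,
                       step_mean_crw = 60, step_mean_brw = 150,
                       crw_rho = 0.8, brw_kappa = 8,
                       gps_noise_sd = 8,
                       site = c(2.3667, 16.2667),
                       swamp_polygon = NULL,
                       weather_p = 0.5,
                       canopy_mean = 1.42, canopy_sd = 0.39,
                       understorey_mean = 1.52, understorey_sd = 0.43,
                       feeding_rate = 0.3,
                       dist_mean = 457.84, dist_sd = 530.71) {
  if (is.null(swamp_polygon)) {
    cx <- 2300; cy <- 2300; h <- 250
    swamp_polygon <- cbind(x = c(cx - h, cx + h, cx + h, cx - h),
                           y = c(cy - h, cy - h, cy + h, cy + h))
  }
  stopifnot(crw_rho >= 0, crw_rho < 1, brw_kappa >= 0, gps_noise_sd > 0,
            weather_p >= 0, weather_p <= 1,
            feeding_rate >= 0, feeding_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @keywords internal
#' von Mises sampler (Best & Fisher 1979 rejection algorithm).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' @keywords internal
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' @keywords internal
day_times <- function(date, interval_min = 20, tz = "Etc/GMT-1") {
  start <- as.POSIXct(paste(date, "06:00:00"), tz = tz)
  start + seq(0, 12 * 3600, by = interval_min * 60)
}

#' @keywords internal
#' Scans in synchrony with the fixes; feeding events at cfg$feeding_rate.
synth_scans <- function(times, cfg, species_pool = paste0("sp", 1:6)) {
  ns <- length(times)
  weather <- stats::rbinom(ns, 1, cfg$weather_p)
  canopy <- round(rtrunc_norm(ns, cfg$canopy_mean, cfg$canopy_sd, 0, 3), 2)
  under <- round(rtrunc_norm(ns, cfg$understorey_mean, cfg$understorey_sd, 0, 3), 2)
  feeds <- stats::runif(ns) < cfg$feeding_rate
  nvis <- pmax(3, stats::rpois(ns, 6))
  sp <- sample(species_pool, ns, replace = TRUE)
  nf <- ifelse(feeds, ceiling(nvis / 2), 0)
  behav_scan_table(
    time = times, n_adults_visible = nvis,
    species = ifelse(feeds, sp, NA_character_),
    food_type = ifelse(feeds, "stems", NA_character_),
    n_feeding = nf, weather = weather,
    canopy = canopy, understorey = under,
    vegetation = "mixed")
}

#' Generate a tortuous (correlated random walk) foraging day
#'
#' Wrapped-normal CRW sampled every 20 min from 06:00 to 18:00 local time:
#' heading increments `~ N(0, sigma)` with `sigma = sqrt(-2 log(rho))`,
#' gamma step lengths (shape 2), i.i.d. Gaussian GPS noise on each fix, and
#' behavioural scans in synchrony. The noise-free path is stored in the
#' `truth` attribute for recovery scoring.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed (bit-reproducible with `cfg`).
#' @param date Calendar date of the day.
#' @param start Planar start location `c(x, y)`.
#' @return A [daily_track()] with scans; `attr(, "truth")` holds the
#'   noise-free coordinates.
#' @export
generate_crw_day <- function(cfg = sim_config(), seed = 1,
                             date = as.Date("2013-03-01"),
                             start = c(0, 0)) {
  set.seed(seed)
  times <- day_times(date)
  n <- length(times)
  sigma <- if (cfg$crw_rho == 0) NULL else sqrt(-2 * log(cfg$crw_rho))
  turns <- if (is.null(sigma)) stats::runif(n - 1, -pi, pi) else
    stats::rnorm(n - 1, 0, sigma)
  head0 <- stats::runif(1, -pi, pi)
  headings <- head0 + cumsum(c(0, turns[-1]))
  steps <- stats::rgamma(n - 1, shape = 2, scale = cfg$step_mean_crw / 2)
  tx <- start[1] + cumsum(c(0, steps * cos(headings)))
  ty <- start[2] + cumsum(c(0, steps * sin(headings)))
  x <- tx + stats::rnorm(n, 0, cfg$gps_noise_sd)
  y <- ty + stats::rnorm(n, 0, cfg$gps_noise_sd)
  tr <- daily_track(date = date, time = times, x = x, y = y,
                    scans = synth_scans(times, cfg), context = "non-swamp")
  attr(tr, "truth") <- data.frame(x = tx, y = ty)
  tr
}

#' Generate a directed (biased random walk) swamp-approach day
#'
#' The day starts at `start_distance` from the swamp polygon boundary in a
#' uniformly random direction from its centroid; headings are von Mises
#' about the current bearing to `target` and the walk stops at the first
#' fix inside the polygon. GPS noise and synchronous scans as in
#' [generate_crw_day()]. Days that fail to reach the polygon within the
#' dawn-to-dusk fix budget are flagged (`attr(, "reached") == FALSE`).
#'
#' @param cfg A [sim_config()].
#' @param target Planar `c(x, y)` aimed at; default the polygon centroid.
#' @param start_distance Straight-line start distance (m) from the target.
#' @param seed Integer RNG seed.
#' @param date Calendar date.
#' @return A [daily_track()] (context `"swamp"`), with `truth` and
#'   `reached` attributes.
#' @export
generate_brw_day <- function(cfg = sim_config(), target = NULL,
                             start_distance = 2000, seed = 1,
                             date = as.Date("2013-06-01")) {
  stopifnot(start_distance > 0)
  set.seed(seed)
  poly <- cfg$swamp_polygon
  if (is.null(target)) target <- colMeans(poly)
  ang <- stats::runif(1, 0, 2 * pi)
  pos <- target + start_distance * c(cos(ang), sin(ang))
  times_all <- day_times(date)
  n_max <- length(times_all)
  tx <- pos[1]; ty <- pos[2]
  for (i in seq_len(n_max - 1)) {
    bearing <- atan2(target[2] - ty[i], target[1] - tx[i])
    h <- rvonmises(1, bearing, cfg$brw_kappa)
    st <- stats::rgamma(1, shape = 2, scale = cfg$step_mean_brw / 2)
    tx <- c(tx, tx[i] + st * cos(h))
    ty <- c(ty, ty[i] + st * sin(h))
    if (mgcv::in.out(poly, cbind(tx[i + 1], ty[i + 1]))) break
  }
  n <- length(tx)
  reached <- mgcv::in.out(poly, cbind(tx[n], ty[n]))
  x <- tx + stats::rnorm(n, 0, cfg$gps_noise_sd)
  y <- ty + stats::rnorm(n, 0, cfg$gps_noise_sd)
  tr <- daily_track(date = date, time = times_all[1:n], x = x, y = y,
                    scans = synth_scans(times_all[1:n], cfg),
                    context = "swamp")
  attr(tr, "truth") <- data.frame(x = tx, y = ty)
  attr(tr, "reached") <- reached
  tr
}

#' Generate a beta-regression dataset with known truth
#'
#' Covariates mimic the field dataset: overcast weather `Bernoulli(p)`,
#' openness scores truncated normal at the reported moments then z-scaled,
#' travelled distance log-normal moment-matched to the reported raw
#' mean/SD then log-z-scaled, `cos(sun elevation)` evaluated at times
#' uniform over daylight at the site, and swamp context `Bernoulli(8/657)`.
#' Responses are Beta with mean `plogis(X beta)` and precision `phi`.
#'
#' @param beta Length-7 coefficient vector: intercept, `I_w`, `Z_u`, `Z_c`,
#'   `cos_e`, `Z_d`, `I_cx` (logit scale).
#' @param phi Precision parameter (> 0).
#' @param n Number of rows (>= 30).
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List: `design` (data.frame in the same column order), `response`
#'   (vector in (0,1)), `truth` (list with `beta`, `phi`, `mu`).
#' @export
generate_betareg_dataset <- function(beta, phi, n = 657,
                                     cfg = sim_config(), seed = 1) {
  stopifnot(length(beta) == 7, phi > 0, n >= 30)
  set.seed(seed)
  I_w <- stats::rbinom(n, 1, cfg$weather_p)
  canopy <- rtrunc_norm(n, cfg$canopy_mean, cfg$canopy_sd, 0, 3)
  under <- rtrunc_norm(n, cfg$understorey_mean, cfg$understorey_sd, 0, 3)
  cv2 <- log(1 + (cfg$dist_sd / cfg$dist_mean)^2)
  dist <- stats::rlnorm(n, meanlog = log(cfg$dist_mean) - cv2 / 2,
                        sdlog = sqrt(cv2))
  day <- sample(seq(as.Date("2012-10-01"), as.Date("2015-01-31"), by = 1),
                n, replace = TRUE)
  tod <- as.POSIXct(paste(day, "06:30:00"), tz = "Etc/GMT-1") +
    stats::runif(n, 0, 11 * 3600)
  cos_e <- sun_position(tod, cfg$site[1], cfg$site[2])$cos_elevation
  I_cx <- stats::rbinom(n, 1, 8 / 657)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  design <- data.frame(I_w = I_w, Z_u = z(under), Z_c = z(canopy),
                       cos_e = cos_e, Z_d = z(log(dist)), I_cx = I_cx)
  mu <- stats::plogis(drop(cbind(1, as.matrix(design)) %*% beta))
  yr <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  # guard against numerical underflow to the boundary
  eps <- .Machine$double.eps
  yr <- pmin(pmax(yr, eps), 1 - eps)
  list(design = design, response = yr,
       truth = list(beta = beta, phi = phi, mu = mu),
       raw = data.frame(canopy = canopy, understorey = under,
                        distance = dist))
}

#' Generate multinomial feeding-scan tables per habitat
#'
#' Draws `n_per_habitat` deduplicated feeding observations per habitat from
#' its category distribution, so the true Morisita-Horn similarity between
#' habitats is computable from the profiles themselves.
#'
#' @param habitat_profiles Named list: habitat -> named probability vector
#'   over `"species|food_type"` categories (each sums to 1).
#' @param n_per_habitat Named (or recycled) integer vector of sample sizes.
#' @param seed Integer RNG seed.
#' @return data.frame `habitat`, `species`, `food_type`, `time` (synthetic
#'   hourly stamps so the rows are already hour-unique).
#' @export
generate_feeding_scans <- function(habitat_profiles, n_per_habitat,
                                   seed = 1) {
  set.seed(seed)
  if (length(n_per_habitat) == 1)
    n_per_habitat <- rep(n_per_habitat, length(habitat_profiles))
  out <- list()
  t0 <- as.POSIXct("2013-01-01 06:00:00", tz = "Etc/GMT-1")
  for (h in seq_along(habitat_profiles)) {
    prof <- habitat_profiles[[h]]
    stopifnot(abs(sum(prof) - 1) < 1e-8)
    n <- n_per_habitat[h]
    if (n == 0) next
    cats <- sample(names(prof), n, replace = TRUE, prob = prof)
    parts <- strsplit(cats, "|", fixed = TRUE)
    out[[length(out) + 1]] <- data.frame(
      habitat = names(habitat_profiles)[h],
      species = vapply(parts, `[`, "", 1),
      food_type = vapply(parts, `[`, "", 2),
      time = t0 + 3600 * seq_len(n))
  }
  if (length(out) == 0)
    return(data.frame(habitat = character(), species = character(),
                      food_type = character(),
                      time = as.POSIXct(character())))
  do.call(rbind, out)
}

#' Deterministic beta-regression fixture
#'
#' A fixed dataset built without any RNG (low-discrepancy covariate
#' sequences, Beta-quantile responses), used to compare fitters across
#' implementations bit-for-bit. Identical on every platform and run.
#'
#' @param n Number of rows.
#' @return data.frame with response `y` and the six design columns.
#' @export
betareg_fixture <- function(n = 200) {
  gold <- (sqrt(5) - 1) / 2
  i <- seq_len(n)
  I_w <- i %% 2
  Z_u <- stats::qnorm(((i * 7) %% n + 0.5) / n)
  Z_c <- stats::qnorm(((i * 13) %% n + 0.5) / n)
  cos_e <- 0.15 + 0.8 * ((i * gold) %% 1)
  Z_d <- stats::qnorm(((i * 29) %% n + 0.5) / n)
  I_cx <- as.numeric(((i * 11) %% n) < n / 80)
  X <- cbind(1, I_w, Z_u, Z_c, cos_e, Z_d, I_cx)
  beta <- c(0.99, -0.23, 0.08, 0.02, 0.78, -0.23, 0.20)
  phi <- 3.91
  mu <- stats::plogis(drop(X %*% beta))
  u <- (i * (sqrt(2) - 1)) %% 1
  u <- pmin(pmax(u, 1e-4), 1 - 1e-4)
  y <- stats::qbeta(u, mu * phi, (1 - mu) * phi)
  data.frame(y = y, I_w = I_w, Z_u = Z_u, Z_c = Z_c,
             cos_e = cos_e, Z_d = Z_d, I_cx = I_cx)
}
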