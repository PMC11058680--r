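test_that("adjusted_straightness matches the shrinkage formula", {
  expect_equal(adjusted_straightness(0.5, 2), 0.5)          # fixed point
  expect_equal(adjusted_straightness(1, 657), 656.5 / 657)
  expect_equal(adjusted_straightness(0, 657), 0.5 / 657)

  # strictly increasing, maps [0,1] into (0,1)
  s <- seq(0, 1, by = 0.05)
  out <- adjusted_straightness(s, 100)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out < 1))
  expect_error(adjusted_straightness(1.2, 10), "\\[0, 1\\]")
  expect_error(adjusted_straightness(0.5, 0), "n_bouts")
})

test_that("prepare_design z-scales with the sample-SD convention", {
  mk_bout <- function(dist, canopy, under, w = 0, ce = 0.5, ctx = "non-swamp") {
    structure(list(straightness = 0.7, path_length = dist, weather = w,
                   canopy = canopy, understorey = under, cos_elevation = ce,
                   context = ctx), class = "movement_bout")
  }
  # distances {100,100,100,100e}: after log and sample-SD scaling the
  # z-scores are {-0.5,-0.5,-0.5,1.5}
  bouts <- list(mk_bout(100, 1.0, 1.0), mk_bout(100, 1.5, 2.0),
                mk_bout(100, 2.0, 1.2), mk_bout(100 * exp(1), 1.2, 1.7))
  prep <- prepare_design(bouts)
  expect_equal(prep$design$Z_d, c(-0.5, -0.5, -0.5, 1.5))
  expect_equal(mean(prep$design$Z_c), 0)
  expect_equal(sd(prep$design$Z_c), 1)
  expect_equal(prep$response$n_bouts, 4)
  expect_equal(prep$response$s_adj, rep(adjusted_straightness(0.7, 4), 4))
  # pre-scaling moments are reported
  expect_equal(prep$scaling$mean[prep$scaling$variable == "canopy"],
               mean(c(1, 1.5, 2, 1.2)))

  # zero variance is an error
  flat <- list(mk_bout(100, 1, 1), mk_bout(200, 1, 2), mk_bout(300, 1, 3))
  expect_error(prepare_design(flat), "zero variance")
})

test_that("fit_beta_regression recovers a symmetric intercept-only model", {
  set.seed(101)
  y <- rbeta(400, 2, 2)
  fit <- fit_beta_regression(data.frame(dummy = rnorm(400)), y)
  expect_true(fit$converged)
  expect_equal(plogis(fit$coefficients[["(Intercept)"]]), 0.5,
               tolerance = 0.05)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_error(fit_beta_regression(data.frame(a = 1:5 / 10), c(0, .2, .4, .6, .8)),
               "strictly inside")
})

test_that("fitted model beats nested models in likelihood; LRT mechanics", {
  d <- generate_betareg_dataset(c(1, -0.3, 0.1, 0, 0.8, -0.2, 0.2),
                                phi = 4, n = 300, seed = 55)
  full <- fit_beta_regression(d$design, d$response)
  red <- fit_beta_regression(d$design[, c("Z_d", "I_cx")], d$response)
  expect_gte(full$loglik, red$loglik)

  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 4)
  expect_gte(lrt$chi2, 0)

  # identical models: chi2 = 0 within numerical tolerance -> df error
  expect_error(likelihood_ratio_test(red, full), "more parameters|nested")

  one <- fit_beta_regression(d$design[, names(d$design) != "I_w"], d$response)
  expect_equal(likelihood_ratio_test(full, one)$df, 1)

  # non-nested designs are rejected
  other <- d$design[, c("Z_d", "I_cx")]
  names(other) <- c("Q1", "Q2")
  bad <- fit_beta_regression(other, d$response)
  expect_error(likelihood_ratio_test(full, bad), "nested")
})

test_that("Wald CIs are estimate +/- 1.96 se and phi is positive", {
  d <- generate_betareg_dataset(c(0.99, -0.23, 0.08, 0.02, 0.78, -0.23, 0.20),
                                phi = 3.91, n = 657, seed = 42)
  fit <- fit_beta_regression(d$design, d$response)
  expect_true(fit$converged)
  expect_gt(fit$coefficients[["phi"]], 0)
  expect_equal(unname(fit$ci95[, "lo"]), unname(fit$coefficients - 1.96 * fit$se))
  expect_equal(unname(fit$ci95[, "hi"]), unname(fit$coefficients + 1.96 * fit$se))
  expect_true(is.finite(fit$loglik))
})

test_that("consistency: precision 1000 shrinks residuals and bias", {
  truth <- c(0.99, -0.23, 0.08, 0.02, 0.78, -0.23, 0.20)
  d <- generate_betareg_dataset(truth, phi = 1000, n = 657, seed = 7)
  expect_lt(sd(d$response - d$truth$mu), 0.02)
  fit <- fit_beta_regression(d$design, d$response)
  expect_lt(max(abs(fit$coefficients[1:7] - truth)), 0.1)
})

test_that("marginal means average predictions on the response scale", {
  d <- generate_betareg_dataset(c(1, -0.4, 0, 0, 0.5, -0.2, 0.1),
                                phi = 5, n = 400, seed = 12)
  fit <- fit_beta_regression(d$design, d$response)
  mm <- marginal_means(fit, "I_w")
  # negative weather coefficient: overcast marginal mean is lower
  expect_lt(mm[["1"]], mm[["0"]])
  # hand-computed averaging
  nd0 <- fit$design; nd0$I_w <- 0
  expect_equal(mm[["0"]], mean(predict(fit, nd0)))

  # all-zero slopes: both levels collapse to plogis(intercept)
  set.seed(3)
  y0 <- rbeta(300, 0.7 * 6, 0.3 * 6)
  f0 <- fit_beta_regression(data.frame(I_w = rbinom(300, 1, 0.5)), y0)
  f0$coefficients["I_w"] <- 0
  m0 <- marginal_means(f0, "I_w")
  expect_equal(unname(m0[["0"]]), unname(m0[["1"]]))

  expect_warning(marginal_means(fit, "I_w", levels = 2), "support")
  expect_error(marginal_means(fit, "nope"), "unknown")
})

test_that("simulated Table-1 world yields a ~0.04 weather marginal gap", {
  truth <- c(0.99, -0.23, 0.08, 0.02, 0.78, -0.23, 0.20)
  gaps <- vapply(1:10, function(s) {
    d <- generate_betareg_dataset(truth, phi = 3.91, n = 657, seed = 900 + s)
    fit <- fit_beta_regression(d$design, d$response)
    mm <- marginal_means(fit, "I_w")
    mm[["1"]] - mm[["0"]]
  }, numeric(1))
  expect_lt(median(gaps), 0)
  expect_gt(abs(median(gaps)), 0.02)
  expect_lt(abs(median(gaps)), 0.07)
})
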