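# Beta regression of movement-bout straightness: response transform,
# design preparation, ML fitting with logit link and constant precision,
# likelihood-ratio tests and marginal means.

#' Adjusted straightness transform
#'
#' Shrinks raw straightness values in `[0, 1]` into the open interval
#' required by the Beta likelihood: `s' = (s (N - 1) + 0.5) / N`, where `N`
#' is the number of bouts entering the analysis.
#'
#' @param s Straightness values in `[0, 1]`.
#' @param n_bouts Number of bouts in the analysed dataset (`N >= 1`).
#' @return Adjusted values, strictly inside `(0, 1)`.
#' @export
adjusted_straightness <- function(s, n_bouts) {
  if (any(s < 0 | s > 1)) stop("straightness must lie in [0, 1]")
  if (n_bouts < 1) stop("n_bouts must be >= 1")
  (s * (n_bouts - 1) + 0.5) / n_bouts
}

#' @keywords internal
zscale <- function(v, label) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("zero variance in column '", label, "': cannot z-scale")
  list(z = (v - mean(v)) / s, mean = mean(v), sd = s)
}

#' Prepare the straightness-model design matrix from bouts
#'
#' Builds the regression dataset: binary weather `I_w` (1 overcast),
#' z-scaled understorey `Z_u` and canopy `Z_c` openness, unscaled
#' `cos(sun elevation)`, z-scaled log travelled distance `Z_d`, and binary
#' context `I_cx` (1 swamp day). The response is the adjusted straightness
#' with `N` equal to the number of rows. Z-scaling uses the sample SD
#' (n - 1 denominator); pre-scaling moments are reported for audit.
#'
#' @param bouts List of `movement_bout`s with covariates attached
#'   (see [attach_bout_covariates()]).
#' @return List: `design` (data.frame `I_w,Z_u,Z_c,cos_e,Z_d,I_cx`),
#'   `response` (`s`, `s_adj`, `n_bouts`), `scaling` (pre-scaling
#'   means/SDs).
#' @export
prepare_design <- function(bouts) {
  n <- length(bouts)
  if (n == 0) stop("no bouts to prepare")
  g <- function(f) vapply(bouts, function(b) as.numeric(b[[f]]), numeric(1))
  s <- g("straightness")
  dist <- g("path_length")
  if (any(dist <= 0)) stop("all travelled distances must be positive")
  zc <- zscale(g("canopy"), "canopy")
  zu <- zscale(g("understorey"), "understorey")
  zd <- zscale(log(dist), "log distance")
  ctx <- as.numeric(g_chr(bouts, "context") == "swamp")
  design <- data.frame(I_w = g("weather"), Z_u = zu$z, Z_c = zc$z,
                       cos_e = g("cos_elevation"), Z_d = zd$z, I_cx = ctx)
  response <- list(s = s, s_adj = adjusted_straightness(s, n), n_bouts = n)
  scaling <- data.frame(
    variable = c("canopy", "understorey", "log_distance"),
    mean = c(zc$mean, zu$mean, zd$mean),
    sd = c(zc$sd, zu$sd, zd$sd))
  list(design = design, response = response, scaling = scaling)
}

#' @keywords internal
g_chr <- function(bouts, f) vapply(bouts, function(b) as.character(b[[f]]), character(1))

#' @keywords internal
#' Beta log-likelihood, gradient in (beta, log phi)
betareg_loglik <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[1:p])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
      (a - 1) * log(y) + (b - 1) * log1p(-y))
}

#' @keywords internal
betareg_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[1:p])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- sum(mu * (ystar - mustar) + log1p(-y) -
              digamma((1 - mu) * phi) + digamma(phi))
  c(gb, gphi * phi)   # chain rule for log-phi parametrisation
}

#' Fit a beta regression by maximum likelihood
#'
#' Beta observation model with mean `mu_i = plogis(x_i' beta)` and a single
#' constant precision `phi` (shapes `mu_i phi`, `(1 - mu_i) phi`).
#' Optimised by BFGS with the analytic gradient in `(beta, log phi)`;
#' starting values are `beta_0 = logit(mean(y))`, other coefficients 0, and
#' a method-of-moments `phi`. Up to three jittered restarts on
#' non-convergence (gradient norm `>= 1e-6`). Standard errors come from the
#' inverse observed information on the `(beta, phi)` scale; 95% CIs are
#' Wald, `estimate +/- 1.96 se`.
#'
#' @param design data.frame (or matrix) of covariate columns; an intercept
#'   is added automatically.
#' @param response Numeric response strictly inside `(0, 1)` (use
#'   [adjusted_straightness()]), or the `response` list from
#'   [prepare_design()].
#' @return Object of class `betareg_fit`: `coefficients` (named, including
#'   `(Intercept)` and `phi`), `se`, `ci95`, `loglik`, `n`, `converged`,
#'   `fitted`, plus the model frame for downstream tests.
#' @export
fit_beta_regression <- function(design, response) {
  y <- if (is.list(response) && !is.null(response$s_adj)) response$s_adj else response
  y <- as.numeric(y)
  if (any(y <= 0 | y >= 1))
    stop("responses must be strictly inside (0, 1); apply adjusted_straightness")
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("more parameters than observations")

  mu0 <- mean(y)
  phi0 <- max(mu0 * (1 - mu0) / stats::var(y) - 1, 0.1)
  start <- c(stats::qlogis(mu0), rep(0, p - 1), log(phi0))

  best <- NULL
  for (attempt in 0:3) {
    th0 <- if (attempt == 0) start else
      start + stats::rnorm(length(start), 0, 0.25)
    opt <- try(stats::optim(th0, fn = betareg_loglik, gr = betareg_grad,
                            X = X, y = y, method = "BFGS",
                            control = list(fnscale = -1, maxit = 500,
                                           reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    # Newton polish on the numerical Hessian to drive the gradient to zero
    th <- opt$par; ll <- opt$value
    for (it in 1:25) {
      g <- betareg_grad(th, X, y)
      if (max(abs(g)) < 1e-8) break
      Hn <- try(stats::optimHess(th, betareg_loglik, betareg_grad, X = X, y = y),
                silent = TRUE)
      if (inherits(Hn, "try-error")) break
      step <- try(solve(Hn, g), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      cand <- th - step
      llc <- betareg_loglik(cand, X, y)
      half <- 0
      while ((!is.finite(llc) || llc < ll - 1e-12) && half < 20) {
        step <- step / 2; cand <- th - step
        llc <- betareg_loglik(cand, X, y); half <- half + 1
      }
      if (!is.finite(llc) || llc < ll - 1e-12) break
      th <- cand; ll <- llc
    }
    gn <- max(abs(betareg_grad(th, X, y)))
    if (is.null(best) || ll > best$value) best <- list(par = th, value = ll)
    if (gn < 1e-6) break
  }
  if (is.null(best)) stop("beta regression optimisation failed on all starts")
  theta <- best$par
  converged <- max(abs(betareg_grad(theta, X, y))) < 1e-6

  est <- c(theta[1:p], phi = exp(theta[p + 1]))
  names(est) <- c(colnames(X), "phi")

  # observed information on the (beta, phi) scale
  ll_nat <- function(par) {
    betareg_loglik(c(par[1:p], log(par[p + 1])), X, y)
  }
  H <- stats::optimHess(est, ll_nat, control = list(fnscale = -1))
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(est)

  eta <- drop(X %*% theta[1:p])
  structure(list(coefficients = est, se = se,
                 ci95 = cbind(lo = est - 1.96 * se, hi = est + 1.96 * se),
                 vcov = V,
                 loglik = best$value, n = n, df = p + 1,
                 converged = converged, fitted = stats::plogis(eta),
                 design = as.data.frame(design), response = y),
            class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("Beta regression (logit link, constant precision), n = %d\n", x$n))
  tab <- data.frame(Est = round(x$coefficients, 4), SE = round(x$se, 4),
                    lo95 = round(x$ci95[, "lo"], 4),
                    hi95 = round(x$ci95[, "hi"], 4))
  print(tab)
  cat(sprintf("logLik = %.3f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.betareg_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Likelihood-ratio test between nested beta regressions
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` on the difference in parameter
#' count, with the p-value from the upper chi-square tail. Covers
#' full-vs-null comparisons (several predictors dropped at once), drop-one
#' tests for per-variable chi-square statistics, and interaction tests.
#'
#' @param full,reduced `betareg_fit` objects on the same response; the
#'   reduced design columns must be a subset of the full design columns.
#' @return List: `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!all(names(reduced$design) %in% names(full$design)))
    stop("models are not nested: reduced design has columns absent from full")
  if (full$n != reduced$n || !isTRUE(all.equal(full$response, reduced$response)))
    stop("models must be fitted to the same response vector")
  df <- full$df - reduced$df
  if (df < 1) stop("full model must have more parameters than reduced")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Predict mean straightness from a fitted beta regression
#'
#' @param object A `betareg_fit`.
#' @param newdata data.frame with the fitted design's columns.
#' @param ... Unused.
#' @return Predicted means on the response scale.
#' @export
predict.betareg_fit <- function(object, newdata = object$design, ...) {
  X <- cbind(1, as.matrix(newdata[, names(object$design), drop = FALSE]))
  p <- ncol(X)
  stats::plogis(drop(X %*% object$coefficients[1:p]))
}

#' Marginal (population-averaged) means for a factor
#'
#' For each requested level, sets the factor column to that level in every
#' observed row, predicts the mean response, and averages on the response
#' scale — the predicted straightness at that level "when the effects of
#' other covariates are averaged".
#'
#' @param fit A `betareg_fit`.
#' @param factor Name of a design column.
#' @param levels Values at which to evaluate it (default `c(0, 1)`).
#' @return Named numeric vector of marginal means.
#' @export
marginal_means <- function(fit, factor, levels = c(0, 1)) {
  if (!factor %in% names(fit$design)) stop("unknown design column: ", factor)
  obs <- fit$design[[factor]]
  out <- vapply(levels, function(lv) {
    if (!lv %in% obs && (lv < min(obs) || lv > max(obs)))
      warning("level ", lv, " outside observed support of ", factor)
    nd <- fit$design
    nd[[factor]] <- lv
    mean(predict(fit, nd))
  }, numeric(1))
  names(out) <- as.character(levels)
  out
}
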