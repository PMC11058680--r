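# Backward straightness profiles and their loess smoothing.

#' Select the profile anchor of a classified day
#'
#' Swamp days anchor at the swamp entry fix; all other days anchor at the
#' fix farthest (planar distance) from the day's first fix, ties broken
#' toward the earliest such fix.
#'
#' @param track A [daily_track()].
#' @param classification Result of [classify_day()], or `NULL` for a
#'   non-swamp day.
#' @return Integer index of the anchor fix in `track$fixes`.
#' @export
select_anchor <- function(track, classification = NULL) {
  fx <- track$fixes
  if (nrow(fx) < 2) stop("select_anchor needs at least 2 fixes")
  if (!is.null(classification) && classification$context == "swamp")
    return(classification$entry_index)
  d <- sqrt((fx$x - fx$x[1])^2 + (fx$y - fx$y[1])^2)
  which.max(d)  # which.max returns the earliest maximiser
}

#' Backward evolution of straightness towards an anchor
#'
#' For each fix preceding the anchor, the straightness of the sub-path from
#' that fix to the anchor, against the backward path distance (travelled
#' path length from the fix to the anchor). A movement deliberately directed
#' at the anchor keeps this profile near 1 out to the distance at which the
#' decision to move was made.
#'
#' @param track A [daily_track()].
#' @param anchor_index Index of the anchor fix.
#' @return data.frame `backward_distance`, `straightness`, ordered by
#'   increasing backward distance (0 rows if the anchor is the first fix).
#' @export
backward_straightness <- function(track, anchor_index) {
  fx <- track$fixes
  stopifnot(anchor_index >= 1, anchor_index <= nrow(fx))
  if (anchor_index == 1)
    return(data.frame(backward_distance = numeric(), straightness = numeric()))
  seg <- sqrt(diff(fx$x[1:anchor_index])^2 + diff(fx$y[1:anchor_index])^2)
  # cumulative path length from fix i to the anchor
  back <- rev(cumsum(rev(seg)))
  bee <- sqrt((fx$x[anchor_index] - fx$x[1:(anchor_index - 1)])^2 +
              (fx$y[anchor_index] - fx$y[1:(anchor_index - 1)])^2)
  ok <- back > 0
  out <- data.frame(backward_distance = back[ok],
                    straightness = bee[ok] / back[ok])
  out[order(out$backward_distance), ]
}

#' Pool backward profiles over many days
#'
#' @param tracks List of [daily_track()]s.
#' @param classifications Optional list of [classify_day()] results, matched
#'   by position.
#' @return data.frame `day_id`, `backward_distance`, `straightness`.
#' @export
pool_profiles <- function(tracks, classifications = NULL) {
  out <- lapply(seq_along(tracks), function(i) {
    cl <- if (is.null(classifications)) NULL else classifications[[i]]
    a <- select_anchor(tracks[[i]], cl)
    p <- backward_straightness(tracks[[i]], a)
    if (nrow(p) == 0) return(NULL)
    cbind(day_id = i, p)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' @keywords internal
#' One local weighted quadratic fit; returns fitted value and hat vector
#' norm diagnostics at x0.
local_fit <- function(x, y, x0, q, degree) {
  d <- abs(x - x0)
  dq <- sort(d, partial = q)[q]
  if (dq <= 0) {
    # q or more replicates at x0: fit reduces to their mean
    w <- as.numeric(d == 0)
  } else {
    r <- d / dq
    w <- ifelse(r < 1, (1 - r^3)^3, 0)
  }
  use <- w > 0
  xs <- x[use] - x0
  X <- outer(xs, 0:degree, `^`)
  W <- w[use]
  XtW <- t(X * W)
  A <- XtW %*% X
  # ridge of last resort for numerically singular neighbourhoods
  sol <- tryCatch(solve(A, XtW), error = function(e)
    solve(A + diag(1e-10 * max(diag(A)), ncol(A)), XtW))
  l <- sol[1, ]                      # hat weights on the used points
  list(fit = sum(l * y[use]), l2 = sum(l^2), l = l, use = which(use))
}

#' Loess smoothing of a pooled backward profile
#'
#' Local polynomial regression with tricube weights over the `span` fraction
#' of nearest points (the classical loess estimator, degree 2 by default),
#' evaluated on a regular grid of backward distances. The 95% band is the
#' pointwise normal approximation `fit +/- 1.96 se`, with the residual
#' variance normalised by the loess one-delta correction.
#'
#' @param points data.frame with `backward_distance` and `straightness`.
#' @param span Fraction of points in each local neighbourhood (default 0.10).
#' @param grid_step Grid spacing in metres (default 30).
#' @param degree Local polynomial degree (default 2).
#' @return data.frame `grid`, `fit`, `se`, `lo95`, `hi95`; grid points
#'   outside the data range are not evaluated (no extrapolation).
#' @export
loess_smooth <- function(points, span = 0.10, grid_step = 30, degree = 2) {
  x <- points$backward_distance
  y <- points$straightness
  n <- length(x)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (n < max(10, degree + 2)) stop("too few points to smooth")
  q <- max(degree + 1, floor(n * span + 1e-9))
  q <- min(q, n)

  # residual variance via a pass over the data points themselves
  tr_l <- 0; tr_ll <- 0; rss <- 0
  for (i in seq_len(n)) {
    f <- local_fit(x, y, x[i], q, degree)
    rss <- rss + (y[i] - f$fit)^2
    tr_ll <- tr_ll + f$l2
    tr_l <- tr_l + f$l[match(i, f$use)]
  }
  # delta1 = tr((I-L)'(I-L)) >= 0; clamp roundoff when the smooth
  # nearly interpolates (span*n close to degree+1)
  delta1 <- max(n - 2 * tr_l + tr_ll, .Machine$double.eps)
  sigma2 <- max(rss / delta1, 0)

  g0 <- grid_step * ceiling(min(x) / grid_step)
  grid <- seq(g0, max(x), by = grid_step)
  if (length(grid) == 0) grid <- min(x)
  fit <- se <- numeric(length(grid))
  for (k in seq_along(grid)) {
    f <- local_fit(x, y, grid[k], q, degree)
    fit[k] <- f$fit
    se[k] <- sqrt(sigma2 * f$l2)
  }
  data.frame(grid = grid, fit = fit, se = se,
             lo95 = fit - 1.96 * se, hi95 = fit + 1.96 * se)
}
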