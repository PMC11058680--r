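---
title: "Methods: bout segmentation, backward straightness and the beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bout segmentation, backward straightness and the beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navbouts)
```

## The scientific problem

A cohesive group of ranging animals is followed dawn to dusk; its location
is logged every 20 minutes with a handheld GPS (15–18 m accuracy) in
synchrony with group behavioural scans that record weather (0 blue sky /
1 overcast), canopy and understorey openness (0 closed … 3 open) and who is
feeding on what. The group occasionally undertakes long (> 1500 m) journeys
to a swamp clearing at the periphery of its home range, a unique source of
mineral-rich aquatic plants. Two questions drive the analysis:

* Are the swamp journeys *intentional* — targeted from the start — rather
  than drift followed by opportunistic feeding? This is read off the
  **backward straightness profile**: straightness measured from
  progressively earlier locations to the target stays near 1 for an
  intentional movement, out to the distance at which the decision was made.
* Does the **sun** influence short-range navigation efficiency, either as a
  compass (readable azimuth when elevation is low → effect of cos(e),
  specifically under clear sky) or via illumination for landmark
  recognition (effect of overcast weather and vegetation openness)? This is
  tested by a beta regression of bout straightness.

Because the field data are access-restricted, the package pairs every
analysis stage with a synthetic generator whose statistical structure
matches what the analysis assumes, and all acceptance evidence is
simulation-based parameter recovery rather than reproduction of the
field-data point estimates.

## Track processing

**Projection.** Local equirectangular about the site reference point
(x = R cos(lat₀)·Δλ, y = R·Δφ, R = 6 371 008.8 m). Over a ~7 km² home range
within 1° of the equator the distance error against the great-circle
distance is far below the GPS noise (tested: < 2 m at 2 km). Fixes farther
than 1° from the origin are rejected rather than silently distorted.

**Denoising.** The field rule is that successive locations within 30 m are
one location. The rule is implemented as a deterministic *anchor walk*:
keep the first fix; drop each subsequent fix within 30 m of the current
anchor; a fix beyond 30 m becomes the new anchor. This choice (over, say,
centroid replacement or comparing to the previous raw fix) keeps every
retained location an observed fix, preserves order, needs one pass, and is
idempotent — which the tests assert. It is a design choice, not the only
reading of the field protocol.

**Straightness.** s = beeline / path length over the planar coordinates;
undefined (error) on zero-length paths, which callers must filter.

## Segmentation into movement bouts

Two regimes, matching how the field days differ:

* **Foraging days**: one candidate bout per pair of successive group
  feeding events (a scan with ≥ 3 visible (sub)adults of which at least
  ⌈n/2⌉ feed on the same species — the ceiling is the conservative reading
  of "at least half" for odd n). A bout is kept only if the feeding sites
  are > 50 m apart (excludes sensory-driven moves) and at least one fix
  lies strictly between them (a two-point straightness is meaningless).
* **Directed long-distance days** (start > 1500 m from the swamp, ending
  inside it): consecutive fix triples, extended forward until the
  first–last separation exceeds 50 m. Windows do not overlap — the greedy
  partition keeps bouts disjoint, hence closer to independent for the
  regression; a sliding-window variant would reuse fixes across bouts.
  Trailing fixes that cannot reach 50 m are dropped.

Bout-level covariates (weather, openness) come from the scan nearest the
bout's mid-time, ties to the earlier scan; the attachment rule is not fixed
by the field protocol, and nearest-in-time is the least-assuming option for
20-min synchronous sampling.

## Backward profiles and smoothing

For swamp days the anchor is the swamp entry fix (first fix inside the
polygon); for other days, the fix farthest from the day's first fix (the
two phrasings "farthest location reached" and "farthest from the first
observation" coincide under this reading, which we adopt; ties go to the
earlier fix). Profile points from all days of a group are pooled before
smoothing — the published figure shows one curve per group, and pooling is
the natural way to obtain it.

Smoothing is classical loess: tricube weights over the span·N nearest
points, local quadratic, Gaussian family, evaluated every 30 m with span
0.10, no extrapolation beyond the data range. The implementation is our
own (so that it can be checked *against* `stats::loess` rather than being
it); with `surface = "direct"` the two agree to machine precision on the
fit. The 95% band is the pointwise normal approximation fit ± 1.96·se with
the residual variance normalised by the one-delta correction
n − 2tr(L) + tr(LLᵀ); when the neighbourhood size approaches the number of
local parameters this quantity can round to zero, and it is clamped at
machine epsilon rather than allowed to go negative.

## Solar geometry

The NOAA simplified ephemeris (geometric mean longitude, equation of time,
declination, hour angle) gives elevation and azimuth. Against an
independent Michalsky-algorithm oracle at the site, elevations agree within
0.01° on 50 instants spanning 2012–2015 — far inside the 0.5° requirement,
which itself is generous for a covariate used only through cos(e).
Atmospheric refraction is ignored (< 0.6° at the horizon, negligible for
cos(e)). The site clock is fixed at UTC+1 with no DST.

## The straightness model

Responses are adjusted into the open interval by s′ = (s(N−1)+0.5)/N with
N the number of analysed bouts. The observation model is Beta with mean
μᵢ = logit⁻¹(xᵢᵀβ) and a single constant precision φ (shapes μᵢφ,
(1−μᵢ)φ): "fixed dispersion" is read as no precision covariates, consistent
with a single printed precision row in the reference results.

Design columns: binary overcast I_w; z-scaled understorey Z_u and canopy
Z_c; cos(e) unscaled (already in [0,1]); z-scaled log travelled distance
Z_d and binary swamp context I_cx as controls. Z-scaling uses the sample
SD (n−1); the convention is recorded in the output metadata because oracle
comparisons depend on it.

**Fitting.** BFGS on (β, log φ) with the analytic gradient, started at
β₀ = logit(mean response), other βs 0, method-of-moments φ, followed by
Newton polishing on the numerical Hessian until the gradient norm is below
1e−6 (the convergence criterion); up to three jittered restarts otherwise,
and non-convergence is flagged, never silent. Standard errors are from the
inverse observed information on the (β, φ) scale; CIs are Wald
(estimate ± 1.96·se — reproducing the printed CI arithmetic, which rules
out profile-likelihood intervals). On a deterministic fixture the fitter
agrees with an independent reference implementation to ~1e−8 in every
coefficient.

**Tests.** Likelihood-ratio tests cover full-vs-null (the null keeps the
intercept and the two controls and drops the four test predictors, hence
df = 4), drop-one per-variable χ²(1) statistics, and the three weather
interactions (each df = 1). Mirroring standard reporting practice, the
pipeline's final model drops interactions not significant at α = 0.05 but
always keeps the main effects. Marginal means for a factor set the factor
to each level in all observed rows, predict, and average on the response
scale.

## The synthetic world

The generators encode the stated world once; none of their values were
revisited after seeing test outcomes.

* **Days**: 06:00–18:00 local, fixes every 20 min (37 fixes).
* **GPS noise**: i.i.d. Gaussian, SD 8 m per axis (mean radial error
  ≈ 10 m, 95% ≈ 20 m) — a realistic handheld-under-canopy figure for a
  quoted 15–18 m accuracy.
* **Foraging days**: wrapped-normal correlated random walk with turning
  concentration ρ = 0.8 (σ = √(−2 ln ρ)), gamma(shape 2) steps with mean
  60 m, giving ~1 km daily travel as observed for the study group. Scans
  carry weather ~ Bernoulli(0.5) (the clear/overcast split is not
  published), openness ~ truncated normal at the published moments
  (canopy 1.42 ± 0.39, understorey 1.52 ± 0.43 on [0,3]) and a feeding
  event in 30% of scans (unstated in the field protocol; fixed a priori).
* **Swamp approaches**: von Mises biased random walk (κ = 8) towards the
  polygon centroid, mean step 150 m (journeys cover ≥ 3× the daily norm
  with few stops), started at the drawn distance (the published range is
  1644–2461 m) in a uniform random direction, terminated at polygon entry.
* **Regression datasets**: distance ~ log-normal moment-matched to the
  published raw mean 457.84 / SD 530.71; cos(e) from the real ephemeris at
  times uniform over daylight; context ~ Bernoulli(8/657).

What a green test establishes: that the *procedures* — segmentation rules,
profile machinery, ML fitter, LRT calibration — behave correctly in a
world with the assumed structure. What it does not establish: anything
about the field point estimates themselves (those data are restricted), nor
that real gorilla movement follows CRW/BRW mechanics — the walks are
minimal stand-ins exhibiting the tortuous-vs-directed contrast, not
behavioural claims.

## Numerical choices and degenerate inputs

* Straightness errors on zero path length; the profile machinery drops
  zero-backward-distance points.
* Zero variance in any z-scaled column is an error (scaling undefined).
* Responses at exactly 0 or 1 are rejected by the fitter — the adjusted
  transform is the supported route in.
* Beta draws that underflow to the boundary in the generator are nudged by
  machine epsilon.
* Ties: anchor selection takes the earliest farthest fix; covariate
  attachment takes the earlier scan; `which.max` semantics make both
  deterministic.
* Seeds: every generator takes an explicit integer seed and is
  bit-reproducible given (config, seed).

## Known limitations

* No change-point detection for where the orientation phase begins; the
  profile is descriptive, as in the source methodology.
* No mixed effects (day identity is not modelled); bouts are treated as
  independent, which the non-overlapping segmentation supports but does
  not guarantee.
* No residual diagnostics suite beyond the LRT machinery.
* The hourly feeding dedup keys on (hour, species, food type) — individual
  identity is not in the group-scan data model.
* Whether bouts spanning the midday rest should be excluded is not stated
  in the field protocol and is not implemented.
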