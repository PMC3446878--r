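---
title: "Methods: predicting precipitation d18O from EVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting precipitation d18O from EVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evisoscape)
```

## The problem and the model

Stable-isotope ratios of precipitation (delta-18O, reported in per-mil
against VSMOW) are a spatiotemporal tracer used across hydrology, ecology
and forensics, but station networks are sparse and discontinuous. This
package predicts precipitation d18O from the MODIS Enhanced Vegetation
Index (EVI), which is available globally every 16 days at 250 m. The
premise is that plant growth and precipitation isotopes respond to the
same climatic and topographic drivers, so a vegetation-index summary of the
growing season carries most of the information needed to predict d18O
without modelling the hydrological cycle itself.

The covariate is the *growing-season integrated EVI* (iEVI): the area
under the smoothed EVI curve, in EVI x days, over (part of) the growing
season. The site-level model linking the interval-scale iEVI covariate $x$
to d18O is a kinked quadratic with five constants:

$$\delta^{18}O(x) = -a\,(|x-b| + c)^2 + d\,x - e$$

* $a > 0.0005$ — curvature (per-mil per iEVI^2);
* $20 < b < 300$ — kink location (iEVI units), the only constant that is
  rescaled between growing seasons;
* $-200 < c < 0$ — kink offset (iEVI units); because $c < 0$, the vertex of
  each quadratic branch sits at $x = b + c$ (left branch) and $x = b - c$
  (right branch);
* $-0.4 < d < 0.4$ — linear slope (per-mil per iEVI);
* $0 < e < 100$ — offset (per-mil).

The function is continuous everywhere and differentiable except at
$x = b$, where the slope jumps by $-4ac$. With covariates on both sides of
the kink all five constants are identifiable; with one-branch data only the
three coefficients of that branch's quadratic are, which matters for the
four-point training design discussed below.

## EVI preprocessing

**Upper-envelope Savitzky–Golay smoothing.** Clouds and poor atmospheric
conditions bias vegetation-index composites downward, never upward, so the
smoother should track the *upper envelope* of the data.
`smoothUpperEnvelope()` fits a weighted local polynomial (degree 2 over a
window of 5 composites on each side, following the half-window convention
of the phenology literature this emulates; both are configurable) and then
runs 3 envelope iterations: after each pass, points below the fit are
down-weighted by

$$w_i = \frac{1}{1 + \left(g_i / (s\,\sigma)\right)^2}$$

with $g_i$ the gap below the fit, $\sigma$ the residual standard deviation
of the pass and $s$ the adaptation strength (default 3; larger is more
tolerant). The exact down-weighting kernel of the original desktop tool is
not published, so this rational kernel was chosen for its scale-free
semantics and is swappable. Two numerical choices are deliberate: new
weights are the pointwise *minimum* of the previous and candidate weights,
so the total weight mass is non-increasing across iterations (a testable
invariant), and boundary points are fitted with truncated asymmetric
windows rather than padded data. With unit weights and zero envelope
iterations the filter reduces to classical Savitzky–Golay, which the test
suite verifies against an independent per-window least-squares oracle and
`signal::sgolayfilt()`.

Missing composites are linearly gap-filled and flagged before smoothing;
more than 3 consecutive missing composites is a hard error rather than a
silent interpolation.

**Growing season.** The season is defined on the smoothed curve: the base
level is the mean of the pre- and post-season minima, the amplitude is the
seasonal maximum minus base, and the limits are the crossings of
`base + 0.167 * amplitude`, linearly interpolated between composites. The
published threshold "0.167 (1/6)" could in principle be read either as an
amplitude fraction (the phenology-software convention) or as a time
fraction; this package treats it as an amplitude fraction and exposes the
time fraction separately as the iEVI `startFraction` (below), so the two
readings are independent settings rather than a single conflated constant.

**iEVI.** `computeIevi()` integrates the smoothed curve by exact
trapezoids (with partial intervals at both ends) from
`start + startFraction * (end - start)` to the season end, with
`startFraction = 1/6` by default — the first sixth of the season is green-up
fuelled largely by stored water. `startFraction = 0` gives the
complete-growing-season iEVI used for cross-season transfer.
`aggregateToIntervals()` produces the per-sampling-interval covariates at
whatever temporal scale the precipitation samples have; integration is
additive over partitions by construction. Times are composite mid-points
(start date + 8 days) and integrals are in EVI x days.

## Fitting the site model

`fitIsoModel()` minimises the root of the summed squared residuals
(root-SSE, deliberately *not* divided by n — it is the exact objective of
the original procedure) over a grid of 63 initial-bound cells: seven lower
bounds on the curvature (`a > 0.0005 ... 0.0035` in steps of 0.0005)
crossed with three lower (−0.1, −0.2, −0.3) and three upper (0.1, 0.2, 0.3)
bounds on the slope. The published text states the outer slope bound as
|d| < 0.4 while its grid never exceeds 0.3; both are retained — the grid
drives the search, the outer bound is the configurable clamp. Within each
cell, 30 bound-constrained Levenberg–Marquardt starts (`minpack.lm`) are
drawn uniformly from the cell's box; the cell keeps its best and the global
best across cells wins, reported with its squared Pearson correlation.
Three design details:

* The original procedure repeats the local fit 30 times without a visible
  randomisation mechanism; repeated identical fits cannot differ, so the
  only reading under which the repetition count matters is randomised
  starting points, which is what is implemented (seeded, deterministic).
* Restart streams are seeded per cell, so the best objective is
  non-increasing in the number of restarts — a tested monotonicity
  property — and results are reproducible for any restart count.
* Strict bound inequalities are realised as closed boxes shrunk by 1e-9,
  with an upper curvature cap of 0.01 (the original states none; the cap
  closes the optimisation box and is configurable). Optimizer tolerances
  are 1e-10 on parameters and 1e-12 on the objective, tight enough that
  noise-free recovery is exact to well below the 0.5% acceptance margin.
* With four observations and five parameters the Levenberg–Marquardt
  residual vector is padded with structural zeros; the objective is
  unchanged and the underdetermined fit converges onto the zero-residual
  manifold.

**Cross-season transfer.** The kink location scales with the size of the
growing season: `b_predict = b_model * (iEVI_pred / iEVI_model)` with
complete-growing-season iEVIs, all other constants carried over.
`rescaleParams()` permits the rescaled `b` to leave the fitting bounds:
those bounds constrain model *building*; the transfer rule is exact
arithmetic applied at prediction time, and clamping it would silently bias
predictions for pixels whose seasons differ strongly from the anchor's.

**Training design.** The field protocol fits each site from four
observations of a single growing season: one at the beginning, two in the
middle, one at the end. `selectTrainingPairs()` formalises "beginning /
middle / end" as the observations whose interval midpoints are nearest to
the season-time quantiles {0, 0.4, 0.6, 1} (the source never defines
"middle"; the quantile pair is configurable), ties going to the earlier
observation, selected without replacement.

## Spatial extension

`fitElevationRelation()` is ordinary least squares of d18O on elevation
(the altitude effect), fitted per time step from as few as two anchors;
three anchors at 91, 1676 and 2876 m reproduce the published design.
`predictAtElevation()` flags extrapolation beyond the anchor range.

`buildIsoscape()` extends site functions across a raster: per pixel it
smooths the series, detects the season, integrates the covariate, predicts
with the *nearest anchor in elevation* (with per-pixel `b` rescaling) and
optionally shifts along the lapse relation by the pixel-to-anchor
elevation difference. This scheme was chosen because the published results
name exactly two relationships — the iEVI–d18O function and the
d18O–topography relation; interpolating the five constants in elevation is
a plausible alternative the data model supports (the constants table is
ordinary columns), but it is not the default. Pixels with no detectable
season are masked as nodata. A tested invariant guarantees the raster path
agrees with the scalar pipeline pixel by pixel to 1e-9 per-mil.

Because no GeoTIFF-capable package is part of this package's dependency
set, rasters travel as ESRI ASCII grids (a plain-text, widely supported
single-band format) with a JSON sidecar for CRS and band dates; the
georeferencing contract (CRS string, lower-left corner, cell size, nodata
−9999) is identical to what a GeoTIFF writer would carry.

`neighborhoodSensitivity()` reruns the full fit/predict cycle with each
ring pixel's EVI (Chebyshev distance 1 = 8 pixels at 250 m, distance 2 =
16 at 500 m) against the site's own observations and reports the pooled
mean, standard error and two-sided one-sample t-test of
`r(ring) − r(focal)`.

## Validation harness

`crossValidateNetwork()` reproduces the predictability design: train in
one growing season, rescale `b` per target season, predict every
target-season interval, and report Pearson r at 16-day, monthly, seasonal
and annual scales, per site and pooled. Monthly aggregation is the
interval-length-weighted mean of predictions and observations within the
calendar month of the interval midpoint — time weighting, not
precipitation-amount weighting, so no rainfall model is smuggled in.
Because r is invariant to affine maps of the predictions, b-rescaling
errors that act affinely on predicted d18O cannot inflate r; this is
documented and tested deliberately.

"Extrema" exclusion is undefined in the source beyond a cap of one removal
per season; here it is the observation with the largest absolute robust
z-score (median/MAD) in its season, removed only if |z| > 3, every removal
logged. Constant seasons (zero MAD) are never touched.

## The synthetic study system

`simulateIsoNetwork()` builds the virtual network all tests run on: 13
stations spaced along a 91–2876 m elevation gradient, site constants
obtained by piecewise-linear interpolation of the built-in reference
constants table against station rank (13 sites reproduce the table
exactly), double-logistic EVI cycles whose amplitude shrinks and season
shortens with elevation, Gaussian EVI noise plus negative-only cloud
spikes, roughly monthly sampling intervals (6 per season) inside each
detected growing season, and d18O generated from each site's own model at
the pipeline's own covariates, plus 0.5 per-mil observation noise and
occasional depletion-only heavy-rain outliers (the tropical-cyclone
analogue; 3% by default).

Two generator choices matter for the closure identity:

* Composites sit on a strictly periodic 16-day grid (a 368-day cycle)
  rather than restarting every calendar year. The real product's annual
  restart makes the year-boundary gap leap-dependent (13 vs 14 days),
  which perturbs smoothing windows and season limits between years at the
  1e-7 level — real but irrelevant structure that would mask genuine
  pipeline defects in an identity test.
* One replicate year is simulated on each side of the requested span and
  dropped after smoothing, so retained years carry no filter edge effects
  (the standard padding practice for this family of filters).

With all noise off, every growing season of a site is then numerically
identical, season iEVIs are equal (identity rescale), and the full
simulate → smooth → season → iEVI → fit → predict loop must return r = 1
within 1e-9 at every aggregation scale. This closure test trains on *all*
in-season observations rather than the four-pair field design: with four
points and five parameters the zero-residual fit is non-unique and its
predictions at unseen covariates are not mathematically pinned, so r = 1
is a theorem only when the training covariates cover the prediction ones.
The four-pair design is exercised separately, where its stochastic
behaviour (not an identity) is what is asserted.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: precipitation-amount effects on isotopes,
temperature-driven interannual variability, snow cover, multi-modal or
failed growing seasons, spatially correlated cloud fields, and sensor
georegistration error. In particular each simulated year has exactly one
growing season, so the seasonal and annual validation scales coincide in
synthetic runs; they differ on real data with partial-season sampling.

## Problem sizes and runtimes

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path: 24-point noise-free recovery designs for the
parameter-recovery checks (about a second per site for the full 63-cell x
30-restart sweep), a 13-site 3-year network for the closure identity, 20
replicate 6-site networks for the stochastic comparison, 20 fitter-vs-
lattice instances (1e5-point lattice, 10 observations), and a 20 x 20
pixel scene for the raster/scalar agreement check. The headline field
predictabilities of the original study (annual r = 0.96, monthly 0.80)
were computed on undeposited rain-gauge data and are not recomputable from
first principles here; the package's quantitative anchors are therefore
the printed constants table and the recovery, identity and dominance
properties above.

## Known limitations

* One growing season per year is assumed; bimodal (double-cropping)
  systems need a multi-season detector the smoothing layer does not
  provide.
* The nearest-anchor spatial scheme produces step changes halfway between
  anchor elevations when the lapse adjustment is disabled.
* The elevation relation is linear; inversion layers and rain-shadow
  effects are outside the model family.
* Season detection needs the seasonal amplitude to clear a configurable
  minimum (0.02 EVI by default); sparse deserts and evergreen saturated
  canopies will be masked rather than predicted.
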