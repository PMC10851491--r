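---
title: "Methods: case-crossover effect modification by historical redlining"
author: "holcmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover effect modification by historical redlining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holcmod)
```

## The scientific question

Historically redlined neighbourhoods (HOLC grade D) carry higher present-day
air pollution and heat exposure. `holcmod` targets a different quantity:
*effect modification*. Holding the exposure contrast fixed, is the
exposure–mortality odds ratio larger for residents of redlined block groups?
The estimand is an interaction odds ratio — the multiplicative change in the
PM2.5 (per 10 µg/m³) or extreme-heat odds ratio associated with living in a
grade-D block group.

## Design: time-stratified bidirectional case-crossover

Each death serves as its own control. The referent set of a case day is
every other day in the same calendar month that falls on the same day of the
week, so each stratum has 4 or 5 rows (1 case + 3 or 4 referents). Referents
lie both before and after the case (bidirectional sampling), which removes
confounding by exposure time trends at the cost of a small post-death
sampling bias that is negligible at realistic daily death risks; the
generator's optional `caseSampling = "hazard"` mode exists to demonstrate
that bias. The calendar-month stratification (rather than a ±k-week window)
avoids overlap bias.

Conditioning on one case per stratum gives the conditional logistic
likelihood: the case day's softmax probability among the stratum's rows.
Stratum-constant covariates cancel, which is why the redlined indicator has
no main effect in either model — only its product with the day-varying
exposure is estimable. The package asserts this structurally (a
stratum-constant column leaves the likelihood and score unchanged).

## Models

Two families, fit by `fitClogit()`:

* PM2.5: exposure is the same-day concentration or a k-day moving average
  (k = 2..5, lags 0..k−1), scaled per 10 µg/m³; adjusters are 4-df natural
  cubic splines of daily mean temperature and vapor pressure.
* Extreme heat: exposure is the any-extreme-heat indicator, a specific
  heat-wave day (1st–4th), or a singleton extreme day; the adjuster is the
  vapor-pressure spline only. The temperature spline is deliberately absent
  — the exposure itself is a temperature construct — mirroring the model as
  specified, although the asymmetry with the PM2.5 model is worth noting.

Spline knots sit at the 25th/50th/75th percentiles of the pooled
case + referent covariate, with boundary knots at the range; natural
(linear-tail) constraints apply outside the boundary. The basis is built by
`splines::ns` with this convention pinned, and the tests verify it against
an independent truncated-power construction.

The source equations print the spline terms with a collapsed summation over
a single coefficient; they are implemented as four distinct coefficients per
spline (indices 2–5 and 6–9 in the PM2.5 model), the only reading under
which the interaction coefficient is the 10th (PM2.5) or 6th (heat)
parameter. The intercept cancels in the conditional likelihood and is not
estimated.

## Fitting and inference

`fitClogitRaw()` maximizes the likelihood by Newton–Raphson with
step-halving, using the analytic gradient and Hessian. The linear predictor
is max-subtracted within each stratum before exponentiation, so the
likelihood is overflow-safe. Convergence requires a relative log-likelihood
change below 1e-9 and a maximum absolute score below 1e-6; a coefficient
diverging past |β| = 25 (separation) flags the fit as non-converged with a
warning rather than returning silent output. The covariance is the inverse
observed information at the optimum; intervals are Wald on the log-odds
scale with z = 1.959964, and `orToPercent()` maps an odds ratio to percent
excess daily risk, (OR − 1) × 100.

## Upstream pipeline choices

**Grade crosswalk.** Block populations are binned into the HOLC polygon
containing the block centroid (point-in-polygon on planar projected
coordinates; the package never reprojects). A block group receives the grade
whose bin holds *strictly* more than the threshold share (0.9 default;
0.5/0.99 sensitivity) of its population; ties at the threshold and split
populations are `Ambiguous`; blocks outside all polygons feed an
`Unclassified` bin that competes like a grade. Grade E polygons are carried
through as their own label, never merged into D. Two conventions the source
material leaves open are fixed here: a centroid on a polygon boundary counts
as contained, and a centroid inside overlapping polygons takes the worse
grade (later in A < B < C < D < E), deterministically and with a logged
count. With thresholds above 0.5 the assignment is monotone: raising the
threshold can only turn concrete grades into `Ambiguous`, never the
reverse.

**Exposure aggregation.** PM2.5: mean of grid-centroid values inside each
block polygon, falling back to the Euclidean-nearest grid centroid for
blocks containing none, then a population-weighted average to the block
group. Meteorology: areal-weighted average over grid cells, with cells
modelled as square footprints of one pitch centred on their centroids and
closed ("boundary counts") containment throughout. Daily mean temperature
is (tmin + tmax)/2. All three rules are convex and invariant to rescaling
the weights, and the geometry kernels (ray-cast point-in-polygon,
Sutherland–Hodgman rectangle clipping, shoelace areas) are written in
package R code and validated against winding-angle and Monte-Carlo oracles.

**Calendar.** The meteorology calendar is 365-day: December 31 of leap
years does not exist. A k-day moving average whose window touches a missing
date is missing, and a death whose lag 0–4 window touches it is excluded —
the mechanism behind the corresponding step of the exclusion cascade. The
study window starts January 5 so that lag 4 stays inside the exposure
record.

**Extreme heat.** Cutoffs are per block group per year percentiles of
minimum temperature (type-7 linear interpolation between order statistics —
a convention that must be fixed for reproducibility and is pinned by an
order-statistic oracle test). The comparison is inclusive (a day *meeting*
the cutoff is extreme). Runs of ≥ 2 consecutive extreme days are heat waves
numbered 1, 2, … from the run start; isolated extreme days are singletons.
Run detection works on the continuous calendar, across New Year, with each
day judged against its own year's cutoff — physiology does not reset on
January 1, and midwinter heat waves are rare enough that the choice is
inert; a calendar gap (the missing leap-year Dec 31) does break a run. The
main analysis uses the 95th percentile with 85/90/99 as sensitivity values;
the descriptive tables of the motivating study are headed with the 90th,
so the percentile is a first-class parameter rather than a constant.

**Strata.** A stratum missing any exposure row — case or referent — is
dropped whole and counted, rather than fit with reduced referents. This
mirrors the whole-record exclusions for incomplete lag windows; whether
partially missing strata should instead be retained is genuinely open, and
dropping is the conservative, deterministic choice.

## The synthetic study

`simulateStudy()` generates a city with known ground truth:

* Geography: an 8 × 8 lattice of 1-km square block groups, each holding
  four 500-m blocks with log-normal populations (median 250); an inner
  6 × 6 core carries vertical HOLC bands A/B/C/C/D/D plus a small grade-E
  patch. Band polygons are shifted 0.15 km horizontally and 0.35 km
  vertically off the lattice, so interior band columns resolve cleanly while
  the top and bottom core rows split ~50/50 and become `Ambiguous` at the
  0.9 threshold — emulating the real spatial misalignment of security maps
  and Census geography and the threshold progression it produces.
* Exposures on a 600-m grid: tmin is an annual sinusoid (10 ± 12 °C,
  peaking in mid-July) plus a city-wide AR(1)
  (φ = 0.7, σ = 1.8) and cell noise; tmax = tmin + 8; vapor pressure tracks
  mean temperature (≈ 1.3 kPa at 15 °C); PM2.5 is log-normal
  (median ≈ 8.2 µg/m³) with a city-wide AR(1) day component, plus a
  +1.34 µg/m³ offset inside grade-D polygons, calibrated to the observed
  redlined-vs-overall contrast (≈ 10.95 vs 9.61 µg/m³), and a +0.5 °C
  urban-heat-island offset.
* Cases: each death draws a block group (population-weighted), a month and
  a weekday, then its death day among that month's same-weekday days with
  probability ∝ exp(η) under the true coefficients. This discrete-choice
  sampling is the exact generative counterpart of the conditional
  likelihood, so parameter recovery is a correctly specified test of the
  fitter; true interaction log-odds default to log(1.01) per 10 µg/m³ and
  log(1.02) for heat — the order of magnitude of published estimates, a
  calibration rather than a reproduction. Demographics echo published case
  margins (85.7% White overall vs 53.7% in redlined areas, and so on) but
  are marginal draws only.

What the generator does *not* emulate: spatially autocorrelated baseline
mortality, seasonal mortality trends beyond those induced by the exposures,
realistic joint demographics, multiple cities or states, measurement error
in the exposure surfaces, and residential mobility. Passing tests therefore
demonstrate the correctness of the algorithms and estimator calibration
under a correctly specified generative model — not robustness to the messy
features of real mortality data.

## Validation and problem sizes

The test suite checks every numerical kernel against an independent oracle:
enumeration and finite differences for the conditional likelihood and score,
all-pairs containment for the crosswalk binning, Monte-Carlo point sampling
for areal weights, explicit order statistics for percentiles, run-length
encoding for wave numbering, a truncated-power construction for the spline
basis, and `survival::clogit` for the fitter. Closed forms pin the rest: a
1:1 binary-exposure fixture with 40 vs 20 discordant strata must return an
odds ratio of exactly 2, and a null generator must place cases uniformly in
their referent sets.

Calibration runs use 50 replicates at 20,000 requested strata per model
(mean interaction estimate within 3 Monte-Carlo standard errors of the
truth; Wald 95% coverage within [0.90, 0.98]) and 100 within-stratum
permutation replicates at 4,000 strata for null coverage of the interaction
interval. These sizes keep the full suite within a few minutes on one CPU
while leaving Monte-Carlo error well below the effects being checked.

## Known limitations

* Geometry is planar only; inputs must share one projected CRS, and the
  package will not detect geographic (lon/lat) input.
* Grid cells are modelled as axis-aligned squares; genuinely curvilinear
  grids would need their own footprints.
* The fitter targets strata of case-crossover size (a handful of rows);
  it enumerates no large-stratum exact likelihood.
* Robust/sandwich variances, distributed-lag nonlinear models and
  cause-specific analyses are out of scope.
* A single census epoch: block populations are fixed over the study years,
  so the population-weights-by-record-year question does not arise in the
  synthetic setting.
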