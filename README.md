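# holcmod

Case-crossover analysis of whether living in a historically redlined
neighbourhood modifies the short-term effects of ambient PM2.5 and extreme
heat on mortality.

In the 1930s the Home Owners' Loan Corporation (HOLC) graded urban
neighbourhoods A ("Best") through D ("Hazardous"); grade-D areas were drawn
in red, hence "redlined". Those grades still predict present-day air
pollution, heat exposure and health. `holcmod` is for environmental
epidemiologists who want to estimate not whether redlined areas are more
*exposed*, but whether their residents are more *susceptible*: does the same
10 µg/m³ of PM2.5, or the same extreme-heat day, carry a larger mortality
risk inside a redlined block group?

## The design and the estimand

Each death is compared with itself on referent days — every other day in the
same calendar month falling on the same day of the week, sampled
bidirectionally (before and after the death). This time-stratified
case-crossover design cancels all fixed and slowly varying confounders by
design. Within each stratum the package maximizes the conditional logistic
likelihood

    Pr(case day | stratum) = exp(η_case) / Σ_days exp(η_day)

with two model families:

* **PM2.5:** η = β₁·PM/10 + ns(TMEAN, 4)·β₂..₅ + ns(VP, 4)·β₆..₉ +
  β₁₀·redlined·PM/10, where PM is the same-day concentration or a 2–5 day
  moving average, TMEAN daily mean temperature, VP vapor pressure, and
  `ns(·, 4)` a 4-df natural cubic spline;
* **extreme heat:** η = β₁·extreme + ns(VP, 4)·β₂..₅ + β₆·redlined·extreme,
  where `extreme` flags days whose minimum temperature meets or exceeds a
  per-block-group, per-year percentile cutoff (95th by default), and may be
  replaced by heat-wave-day (1st–4th consecutive day) or singleton
  indicators.

The interaction coefficient (β₁₀ or β₆) is the estimand: exp(β) is the
multiplicative change in the exposure–mortality odds ratio associated with
residence in a redlined block group. Its main effect is absorbed by the
self-matching and is not (and cannot be) a model term.

Upstream of the models, the package implements the full data pipeline:

* **Crosswalk** — block populations are binned into the HOLC polygon
  containing the block centroid, and a block group is assigned the grade
  holding strictly more than a share threshold (90% default; 50%/99%
  sensitivity) of its population, else `Ambiguous`.
* **Exposure panel** — gridded PM2.5 goes grid centroid → block (mean of
  encompassed centroids, nearest-centroid fallback) → block group
  (population-weighted); gridded meteorology is areal-weighted over square
  cell footprints; the calendar is 365-day (no Dec 31 in leap years), which
  propagates into moving-average missingness and a record exclusion.
* **Exclusion cascade** — external causes, age < 18, coarse geocodes,
  out-of-state residence, deaths outside the study window, zero-population
  block groups, and lag windows touching a missing leap-year Dec 31, each
  counted in a ledger.
* **Synthetic generator** — a seeded city with misaligned HOLC bands,
  seasonal AR(1) exposures elevated in redlined polygons, and death days
  drawn within referent strata with probability ∝ exp(η) under known true
  coefficients, so the whole pipeline is testable without restricted data.

## Worked example

```r
library(holcmod)

study <- simulateStudy(simConfig(seed = 2, nCases = 5000L))
fit <- fitClogit(study$strata, modelSpec("pm25"))
fit
```

```
FitResult (pm25 x redlined ), 4921 strata, converged in 3 iterations
        term       beta       se      or  ci_low ci_high
    exposure  0.0030975 0.037748 1.00310 0.93157  1.0801
   ns_tmean1 -0.1017300 0.437880 0.90327 0.38291  2.1308
   ...
 interaction -0.0426540 0.098645 0.95824 0.78979  1.1626
```

The `exposure` row is the PM2.5 odds ratio per 10 µg/m³ outside redlined
areas; the `interaction` row is the redlined-vs-not multiplicative
modification of that odds ratio. At this deliberately small demo scale
(5,000 strata, one four-year city) the interval is wide: OR 0.9582
(95% CI 0.7898, 1.1626) against a simulated truth of 1.01. The same call
with `modelSpec("heat_any")` gives the extreme-heat interaction, here
1.0368 (95% CI 0.6949, 1.5469) against a truth of 1.02. The acceptance
suite runs the same recovery at 20,000 strata × 50 replicates, where the
mean estimate lands within Monte-Carlo error of the truth and Wald coverage
is nominal.

`orToPercent()` converts an odds ratio to the percent change in daily risk:
`orToPercent(1.0093)` returns `0.93`.

A full sensitivity grid (thresholds × percentiles × subgroups) runs through
`runAnalysis(simConfig(...), analysisPlan(...), dir = "out")`, which writes
`results.csv`, the exclusion ledger, the crosswalk and a JSON manifest.

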