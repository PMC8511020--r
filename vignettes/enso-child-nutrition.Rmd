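---
title: "Estimating ENSO effects on child anthropometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ENSO effects on child anthropometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The El Niño Southern Oscillation (ENSO) shifts temperature and rainfall
across most of the tropics with a lead time that is forecastable months
ahead. Where those shifts depress agricultural income or raise disease
burden, children's short-run nutritional status responds: weight-for-age
(WAZ), weight-for-height (WHZ) and BMI z-scores fall in warm (El Niño-like)
years in most teleconnected places, and rise in the minority of places
where a warm ENSO brings extra rain. `ensoanthro` implements the full
analytical chain needed to estimate that relationship from household-survey
microdata and gridded climate — teleconnection detection, exposure
assignment, survey preparation, fixed-effects panel estimation with two-way
clustered inference, kernel visualization, placebo inference, and
counterfactual attribution — together with a seeded synthetic-world
generator so every stage can be validated against planted ground truth.

## The estimating equation

For child $i$ in country $c$ observed in tropical year $t$:

$$Y_{ict} = \alpha + \beta_n \, \mathrm{NINO}_t
  + \beta_{int} \left[\mathrm{NINO}_t \times I(\mathrm{PosPrecip}_i)\right]
  + \gamma X_{ic} + f(t_{\mathrm{region}}) + FE_{cr} + \varepsilon_{ict}$$

* $\mathrm{NINO}_t$ is the May–December mean of the monthly NINO3.4-style
  SST anomaly index for the child's tropical year (below).
* $I(\mathrm{PosPrecip}_i)$ flags children in first-level administrative
  units where warm ENSO reliably increases rainfall; $\beta_n$ is the
  effect in the dry/neutral majority, $\beta_n + \beta_{int}$ the total
  slope in positive-precipitation areas. The generator plants the total
  slopes (`beta_n`, `beta_p`); the model reports the main effect and the
  interaction contrast.
* $X_{ic}$ are country-specific slopes in mother's education (years) and
  mother's age at the child's birth.
* $f$ holds region-specific linear trends in survey year and
  region-by-interview-month fixed effects; $FE_{cr}$ are country-by-urban
  cells. A `decade_fe` toggle swaps the linear trends for
  decade-by-region indicators; further spec toggles add lagged tropical-year
  exposures (`lags`), age-category-by-exposure interactions
  (`age_categories`, bins 0-5/6-11/12-23/24-35/36-59 months), and an
  unweighted variant (`weighted = FALSE`).
* Standard errors are two-way clustered by tropical year and admin1 unit.

Weighting targets one of two estimands: `average_country` normalizes
DHS-style sampling weights so every country's observations sum to one
(the effect on the average sample country); `average_child` multiplies
those weights by the country's under-5 population (the effect on the
average child). Estimates and standard errors are invariant to rescaling
all weights, and the normalization is pooled per country by default with a
`per_survey` option that first equalizes surveys within a country — the
pooled reading is the more literal one for "sum to unity for each
country", and the option preserves the alternative.

## Exposure assignment and ENSO states

ENSO events develop from late boreal spring, peak near the calendar year's
end and collapse across the next spring ("spring barrier"), so calendar-year
averages would smear one event across two exposures. Exposure is therefore
the arithmetic mean of exactly the eight May–December index values of a
*tropical year*; interviews in January–April inherit the previous year's
exposure (the May boundary is sharp, and a missing month is an error, never
a silent partial mean).

State labels follow the Oceanic Niño Index convention: 3-month centered
rolling means of monthly anomalies within the tropical year, `el_nino`
when the maximum exceeds +0.5 °C, `la_nina` below −0.5 °C, the larger
absolute excursion winning if both occur. Two choices the convention does
not fix:

* *Edge windows* (May and the following April) borrow the adjacent month
  outside the tropical year when the record provides it and are dropped
  otherwise, keeping every window a true 3-month centered mean.
* *Climatology*: a static per-month mean over the whole record is the
  default for synthetic data; `enso_climatology(mode = "moving")`
  re-bases 30-year windows every 5 years in the style of the operational
  product, for records long enough to drift.

Event anomalies quoted for attribution (e.g. +1.92 °C for a very strong
El Niño) are residuals from an OLS linear trend in tropical year; the
detrending window defaults to the full supplied series since no single
window is canonical.

## Teleconnection detection

For each 0.5° pixel, variable and calendar month, the Pearson correlation
across years between the pixel's month-$m$ value and the index at month
$m-2$ (crossing the year boundary when needed). Correlating within calendar
months removes mean seasonality by construction; by default a linear year
trend is also removed from both series first, because a shared warming
trend would otherwise manufacture correlation. p-values use the t
distribution with $n-2$ df, or $n-3$ when detrended — the extra parameter
matters at 30-year samples, and with it the null calibration is exact: with
zero planted loadings the pixel flag rate matches
$P(\mathrm{Bin}(12, 0.05) \ge 3) \approx 0.0196$.

A pixel is teleconnected with ≥ 3 significant months (optionally sign
restricted); a country when **at least 50%** of its population lives in
flagged pixels (weak inequality); an admin1 unit is positive-precip when
**more than 50%** of its land area is in flagged positive-correlation
pixels (strict). The asymmetry is deliberate — both rules are implemented
exactly as stated for their respective aggregation weights — and boundary
cases (exactly 50.0%) are covered by tests. No multiplicity correction is
applied across pixels or months, matching the sample-definition role of
the rule rather than a discovery claim.

## Estimation and inference

The design matrix is sparse (explicit dummy columns); weighted
least-squares solves the normal equations by Cholesky factorization, which
is numerically identical to absorbing the fixed effects and keeps exact
residuals for the sandwich stage. Perfectly collinear columns — e.g. the
region identities implied by a full month-by-region block on top of
country dummies — are pruned by sequential elimination on the weighted
Gram matrix (tolerance $10^{-9}$ relative), earlier columns winning;
the intercept and exposure block come first so they are never pruned, and
dropped names are reported.

Two-way clustered variance is the inclusion–exclusion combination
$V_{year} + V_{admin1} - V_{year \times admin1}$, each term a
cluster-summed score sandwich with a CR1 multiplier
$G/(G-1)\cdot(N-1)/(N-K)$ per dimension. Two properties worth knowing:

* With every observation its own cluster in both dimensions the estimator
  collapses exactly to HC1 heteroskedasticity-robust variance (tested).
* The combination is **not positive semi-definite in general**. If a
  *reported* exposure term draws a non-positive combined variance the run
  aborts with a diagnostic — truncating silently would fabricate
  precision. Nuisance coefficients (FE and control columns) with
  non-positive combined variance get `NA` standard errors and are counted.
  The hazard grows when the fixed-effect cell count approaches the number
  of clusters in a dimension, or when time-constant admin-level intercepts
  dominate cell-level variance; at the study's own geometry (~30 years,
  ~10 admin1 units per country, hundreds of admin clusters) it is rare.

Confidence intervals use ±1.96 SE by default, matching the reporting
convention of symmetric normal intervals; `critical = "t"` substitutes a
t quantile with $\min(G_1, G_2) - 1$ df for a conservative alternative.

The Frisch–Waugh–Lovell route (`fwl_slope`) partials every non-exposure
column out of the outcome and exposure and refits the two-column weighted
regression; agreement with the joint fit to relative error below $10^{-8}$
is asserted in the tests and is also the fast path for the placebo test,
where only the exposure block changes per permutation (the identity
permutation reproduces the observed estimate exactly). The placebo
permutes exposure values across tropical years, preserving all
within-year structure; its rank-based p-value is uniform under a zero
planted effect and small under the published-magnitude planted effect.

The kernel curve residualizes outcome and exposure on the controls-only
model separately for the dry/neutral and positive-precip subsamples and
smooths with an Epanechnikov kernel (`0.75(1-u^2)` on `|u|<1`, exactly
zero outside), bandwidth 0.7 in exposure-residual units. The local
polynomial degree defaults to 1 (local linear) — the standard choice for
boundary bias — and is configurable; pointwise intervals use the local
sandwich variance with kernel-times-observation weights.

## The synthetic world

The generator emulates the *structure* of the study's four inputs:

* **Index**: AR(1) anomalies (coefficient 0.85, innovation SD 0.35 °C)
  with innovation SD scaled seasonally so variance peaks November–January,
  mimicking ENSO phase locking; the simulated series is an SST *anomaly*
  index (mean ~0), the form the ±0.5 °C state thresholds apply to. With
  33 years this yields May–December mean exposures with a spread of a few
  tenths of a degree and regular warm/cold events.
* **Climate grid**: one latitude band per country, contiguous admin1 runs;
  pixel value = climatology + loading × lag-2 index anomaly + noise, with
  precipitation floored at zero. Defaults put the per-month correlation
  near 0.6 for loaded pixels over 30 years (temperature loading 1 °C/°C
  against 0.9 °C noise), a fifth of countries at zero loading as negative
  controls, and a quarter of admin1 units per teleconnected country on
  positive precipitation loadings (±20 mm/°C against 20 mm noise).
* **Geography**: 10 admin1 units per country, matching the study's ratio
  (532 units / 51 countries). This is not cosmetic: inclusion–exclusion
  inference degenerates when admin-cluster counts approach the
  fixed-effect cell count.
* **Surveys**: each teleconnected country is surveyed every third year
  (rotating offsets), children drawn into 25 sampling clusters per wave
  with log-normal cluster weights — a stand-in exercising the weight
  normalization, not an emulation of DHS design effects — uniform
  interview months (an option ties timing to ENSO state for
  timing-robustness experiments), mother covariates, and 0.56% flagged /
  0.57% missing records to exercise filtering.

Outcomes follow the estimating equation with planted slopes at the
published magnitudes (β_n = −0.0251 σ/°C, interaction +0.0733) and noise
in four layers: child (0.1 σ), admin1-by-year (0.005 σ), tropical year
(0.001 σ) and a small persistent admin1 component (0.002 σ).

**Why the noise is small.** The package's recovery experiment must detect
estimator *bias* at 10% of β_n (±0.0025 σ/°C) in a single run at its
designed size (200,000 children, 30 tropical years). The year-level noise
components do not average out with more children, so the defaults are set
by a power calculation to put the experiment's Monte-Carlo SE near half
that band. The cost is realism in dispersion: real WAZ residuals are ~1 σ,
and at the default scale essentially no synthetic child crosses the −2 σ
underweight threshold. Analyses that need threshold variation (prevalence,
linear-probability fits) should switch to the realistic-dispersion regime
(`effect_params = list(child_noise_sd = 1)`), as `scripts/acceptance.R`
does for its underweight quantity; interval *coverage* is checked at the
default scale and is insensitive to it. Passing tests on this generator
therefore demonstrate correctness of the machinery and calibration of its
inference, not that the method would attain any particular precision on
real survey data.

The persistent admin1 component is deliberately the smallest: time-constant
admin intercepts load asymmetrically on the intersection term of the
two-way variance (their within-admin cross-year score products cancel
against the exposure's detrended year pattern), so letting them dominate
cell-level variance degrades inclusion–exclusion positivity without adding
identifying content. Serial dependence that the admin clustering dimension
must guard against is carried by the admin-by-year component instead.

`simulate_world()` plants outcomes with the generator's *true*
positive-precip flags but hands the analyst the map *estimated* from the
simulated grid, so flag misclassification is part of any end-to-end
recovery exercise.

## Problem sizes and seeds

The test suite validates: exact oracles on ≤ 1,000-row panels (dense
normal equations, explicit score outer products); FWL exactness at
n = 5,000; recovery within 10% and interval coverage in [0.85, 0.98] over
200 replicates of 20,000 children; teleconnection calibration on a
500-pixel null grid and power on loaded pixels over ~30 years; placebo
uniformity over 40 null replicates (119 permutations each) and power over
20 planted replicates (199 permutations). Replicates where two-way
inference degenerates are counted against coverage, conservatively. All
randomness flows through explicit integer seeds; two calls with the same
configuration are bit-identical.

## Known limitations

* No migration, mortality selection, or survey-availability response to
  ENSO — the real-world selection concerns — are modeled; the generator
  cannot test robustness to them, only the estimator's behavior under its
  own assumptions.
* Spatial correlation beyond admin1 shocks (e.g. smooth climate-driven
  outcome fields) is absent, so the two clustering dimensions exhaust the
  dependence by construction.
* Weights are log-normal per cluster, a placeholder for DHS design
  effects the source data do not describe.
* The two-way variance can abort on degenerate geometries by design;
  users hitting it should ask whether their cluster counts support
  two-way inference at all rather than force a truncation.
* z-scores are taken as inputs; constructing them from raw
  height/weight against a growth reference is out of scope.
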