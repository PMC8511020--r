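# ensoanthro

Panel estimation of El Niño Southern Oscillation (ENSO) effects on child
anthropometric outcomes, for researchers working at the intersection of
climate variability and population health. The package implements the full
analytical chain around the estimating equation

```
Y_ict = a + b_n NINO_t + b_int [NINO_t x I(PosPrecip_i)] + g X_ic
        + f(t_region) + FE_cr + e_ict
```

where `Y_ict` is a child's weight-for-age / weight-for-height / BMI z-score
(or a WHO threshold indicator such as underweight, WAZ < −2σ), `NINO_t` is
the May–December mean of a monthly NINO3.4-style SST anomaly index assigned
by *tropical year* (May of year t through April of t+1, respecting the ENSO
"spring barrier"), `I(PosPrecip_i)` flags admin1 units where warm ENSO
reliably increases rainfall, `FE_cr` are country-by-urban fixed effects,
`f` carries region-specific linear trends and month-of-interview effects,
and standard errors are two-way clustered by tropical year and admin1 unit.
Observations carry DHS-style sampling weights normalized per country
(average-country estimand) or additionally scaled by under-5 population
(average-child estimand).

Components:

- **Teleconnection detection** — per-pixel, per-calendar-month Pearson
  correlation of gridded temperature/precipitation with the 2-month-lagged
  index; ≥ 3-significant-months pixel rule; country flag at ≥ 50% of
  population, admin1 positive-precip flag at > 50% of land area (strict).
- **Exposure machinery** — tropical-year means, OLS-detrended event
  anomalies, ONI-style El Niño / La Niña labels from 3-month rolling means
  against ±0.5 °C, with static or moving (30-year / 5-year advancing)
  climatologies.
- **Survey preparation** — quality-flag and missingness filtering with a
  removal log, WHO threshold indicators, both weighting schemes.
- **Estimation** — sparse weighted least squares with explicit
  fixed-effect dummies, collinearity pruning, two-way clustered sandwich
  (inclusion–exclusion with CR1 small-sample multipliers),
  Frisch–Waugh–Lovell residualization, Epanechnikov local-polynomial
  curves (bandwidth 0.7), decade/region subsample fits, placebo
  randomization over tropical years.
- **Attribution** — per-child event shifts, children pushed across
  thresholds, intervention-equivalent coverage (effect sizes supplied as
  an editable config after the Bhutta et al. 2008 meta-analysis), and
  SDG-pace arithmetic.
- **Synthetic world** — a seeded generator for all four input streams
  (index, climate grid, geography, survey microdata) with planted
  teleconnections and treatment effects, so the whole pipeline is testable
  without restricted survey microdata.

## Worked example

```r
library(ensoanthro)

cfg   <- world_config(n_children = 200000L, seed = 1L)   # 33 years, 10 countries
world <- simulate_world(cfg, tele = "estimated")         # index, grid, map, surveys
tab   <- prepare_sample(world$children, world$nino, world$tele, outcome = "waz")
estimate_enso_effect(tab, model_spec())
```

prints

```
ENSO panel estimate | outcome: waz | N = 197,777 | R2 = 0.934 | weighted mean = -0.577
clusters: 33 years x 80 admin1 units
       term estimate        se          p ci_lower ci_upper
1:     nino -0.02455 0.0006796 9.696e-286 -0.02588 -0.02322
2: nino_pos  0.07221 0.0017059  0.000e+00  0.06886  0.07555
total slope in positive-precip areas: 0.0477 (SE 0.0014)
pruned collinear columns: 4
```

The generator planted `b_n = −0.0251` σ/°C and an interaction of `+0.0733`
(the published effect magnitudes): the fit recovers both within sampling
error, with the positive-precip flags *estimated* from the simulated grid
rather than read from the generator's truth. A warm event with a +1.92 °C
detrended anomaly then implies `1.92 × (−0.0246) ≈ −0.047` σ for the
average child, and with the published average underweight coefficient
(+0.01 probability/°C) supplied as a scenario input,
`event_effect(1.92, 0.01)` → +1.9 percentage points underweight risk,
`affected_children(0.019, 311e6)` → 5.9 million children, and
`sdg_pace(0.34, 2017, 2030)` → 2.6 percentage points per year of required
prevalence decline.

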