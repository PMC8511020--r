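#!/usr/bin/env Rscript
# Fit the panel model: survey-weighted WLS with country-by-urban fixed
# effects, region trends and month effects, country-specific mother
# controls, the exposure and its positive-precip interaction, two-way
# (tropical year x admin1) clustered SEs. Also: the FWL residual curve with
# Epanechnikov smoothing, decade/region subsample estimates, and the
# placebo randomization test.

suppressMessages({library(ensoanthro); library(data.table)})
tab <- fread("results/estimation_sample.csv")

rows <- list()
for (oc in c("waz", "whz", "bmiz")) {
  tab_oc <- if (oc == "waz") tab else {
    ch <- fread("results/data/children.csv")
    prepare_sample(ch, read_nino_csv("results/data/nino_index.csv"),
                   fread("results/tele_admin1.csv"), outcome = oc)
  }
  res <- estimate_enso_effect(tab_oc, model_spec(outcome = oc))
  print(res)
  rows[[oc]] <- data.table(outcome = oc, res$terms,
                           dep_mean = res$wmean, n = res$n, r2 = res$r2)
}
fwrite(rbindlist(rows), "results/panel_estimates.csv")

curve <- fwl_residual_curve(tab, model_spec(), bandwidth = 0.7)
fwrite(curve, "results/fwl_curve.csv")
fwrite(attr(curve, "histogram"), "results/fwl_curve_histogram.csv")

for (by in c("decade", "region")) {
  strata <- subsample_effects(tab, model_spec(), by = by)
  fwrite(strata, sprintf("results/subsample_%s.csv", by))
  message(sprintf("subsample (%s): estimates in [%.4f, %.4f]",
                  by, min(strata$estimate), max(strata$estimate)))
}

pl <- placebo_randomization(tab, model_spec(), n_perm = 199L, seed = 99L)
print(pl)
fwrite(data.table(draw = pl$draws), "results/placebo_draws.csv")
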