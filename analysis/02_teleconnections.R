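#!/usr/bin/env Rscript
# Detect ENSO teleconnections in the gridded climate: per-pixel monthly
# correlations with the 2-month-lagged index, the >=3-significant-months
# pixel rule, the country population rule (>= 50%) and the admin1 land-area
# rule (> 50%, strict). Writes the pixel/country/admin1 tables that define
# the estimation sample and the positive-precipitation indicator.

suppressMessages({library(ensoanthro); library(data.table)})
nino <- read_nino_csv("results/data/nino_index.csv")
grid <- read_grid_csv("results/data/grid_meta.csv", "results/data/grid_monthly.csv")

tele <- teleconnection_map(grid, nino, lag = 2, alpha = 0.05, min_months = 3)
fwrite(tele$corr_temp, "results/tele_pixel_temp_correlations.csv")
fwrite(tele$corr_precip, "results/tele_pixel_precip_correlations.csv")
fwrite(tele$country, "results/tele_country.csv")
fwrite(tele$admin1, "results/tele_admin1.csv")

truth <- fread("results/data/geography.csv")
tele_acc <- merge(tele$country, unique(truth[, .(country, temp_loading)]))
message(sprintf("countries flagged teleconnected: %d/%d (truth: %d with nonzero loading)",
                sum(tele$country$teleconnected), nrow(tele$country),
                sum(tele_acc$temp_loading != 0)))
pos_acc <- merge(tele$admin1, unique(truth[, .(admin1, precip_loading)]))
message(sprintf("admin1 positive-precip flags: %d/%d; agreement with planted sign: %.1f%%",
                sum(tele$admin1$pos_precip), nrow(tele$admin1),
                100 * mean(pos_acc$pos_precip == (pos_acc$precip_loading > 0))))
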