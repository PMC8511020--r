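#!/usr/bin/env Rscript
# Build the tropical-year exposure table from the monthly index: May-December
# means, OLS-detrended anomalies, and ONI-style El Nino / La Nina / neutral
# state labels from 3-month rolling means against a +/-0.5 degC threshold.

suppressMessages({library(ensoanthro); library(data.table)})
nino <- read_nino_csv("results/data/nino_index.csv")
expo <- build_exposure_table(nino, climatology_mode = "static")
fwrite(expo, "results/exposure_table.csv")

message(sprintf("tropical years: %d (%d El Nino, %d La Nina, %d neutral)",
                nrow(expo), sum(expo$state == "el_nino", na.rm = TRUE),
                sum(expo$state == "la_nina", na.rm = TRUE),
                sum(expo$state == "neutral", na.rm = TRUE)))
strongest <- expo[which.max(detrended_anomaly)]
message(sprintf("strongest warm tropical year: %d (detrended anomaly %+.2f degC)",
                strongest$tropical_year, strongest$detrended_anomaly))
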