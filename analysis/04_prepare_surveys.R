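#!/usr/bin/env Rscript
# Prepare the estimation sample: attach tropical-year exposure and the
# admin1 positive-precip indicator, drop flagged/missing records (logged),
# add WHO threshold indicators, and build average-country weights (DHS-style
# weights normalized to sum to one per country).

suppressMessages({library(ensoanthro); library(data.table)})
children <- read_children_csv("results/data/children.csv")
nino <- read_nino_csv("results/data/nino_index.csv")
tele_admin <- fread("results/tele_admin1.csv")

tab <- prepare_sample(children, nino, tele_admin, outcome = "waz",
                      mode = "average_country")
fwrite(tab, "results/estimation_sample.csv")
log <- attr(tab, "removal_log")
fwrite(log, "results/removal_log.csv")

message(sprintf("sample: %s children; removed %d flagged (%.2f%%), %d missing WAZ (%.2f%%)",
                format(nrow(tab), big.mark = ","),
                log$n[1], 100 * log$frac[1], log$n[2], 100 * log$frac[2]))
message(sprintf("share of sample in positive-precip admin1 units: %.1f%%",
                100 * mean(tab$pos_precip)))
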