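#!/usr/bin/env Rscript
# Simulate the four input streams of the study design: a monthly SST-anomaly
# index, a gridded monthly climate with planted teleconnections, a geography
# table, and rotating child-level survey microdata with planted treatment
# effects. Everything downstream reads only the CSV/JSON artifacts written
# here, mirroring a workflow that starts from NOAA / gridded-climate / DHS
# style inputs.

suppressMessages({library(ensoanthro); library(data.table)})
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- world_config(seed = 20260901L)  # study conditions: 33 years, 200k children
world <- simulate_world(cfg, tele = "estimated")

write_nino_csv(world$nino, "results/data/nino_index.csv")
write_grid_csv(world$grid, "results/data/grid_meta.csv",
               "results/data/grid_monthly.csv")
write_children_csv(world$children, "results/data/children.csv")
fwrite(world$geography, "results/data/geography.csv")
fwrite(world$tele$admin1, "results/data/tele_admin1.csv")
fwrite(world$tele$country, "results/data/tele_country.csv")
write_truth_sidecar(cfg, world$effects, "results/data/truth.json")

message(sprintf("world: %d countries (%d teleconnected by the estimated map), %s children",
                cfg$n_countries, sum(world$tele$country$teleconnected),
                format(nrow(world$children), big.mark = ",")))
message(sprintf("planted effects: beta_n = %.4f, beta_p = %.4f (interaction %.4f)",
                cfg$effect_params$beta$waz[["beta_n"]],
                cfg$effect_params$beta$waz[["beta_p"]],
                cfg$effect_params$beta$waz[["beta_p"]] -
                  cfg$effect_params$beta$waz[["beta_n"]]))
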