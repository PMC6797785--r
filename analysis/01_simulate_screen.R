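#!/usr/bin/env Rscript
# Simulate the primary screen: one 384-well plate in three replicate
# experiments, 5% spiked bfa_like actives, a 10% positional gradient and
# low-level library nuisance activity. Writes the plate map and the
# label-level well truth used by the downstream scoring analyses, plus a
# small rendered image subset for the imaging analyses.

suppressPackageStartupMessages(library(rushscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

params <- default_sim_params(positional_gradient_amplitude = 0.1)
layout <- make_screen_layout(c(16L, 24L), replicates = 3L)
ids <- unique(layout$compound_id[layout$control_role == "sample"])
effects <- assign_screen_effects(ids, active_fraction = 0.05, seed = seed)

message(length(ids), " library compounds, ",
        length(attr(effects, "active")), " spiked actives: ",
        paste(attr(effects, "active"), collapse = ", "))

sim <- simulate_plate(layout, effects, params, seed = seed, render = FALSE)
write_plate_map(layout, "results/plate_map.csv")
write.csv(sim$wells, "results/screen_well_truth.csv", row.names = FALSE)
write.csv(sim$effects, "results/screen_effects_truth.csv", row.names = FALSE)

summaries <- truth_well_summaries(sim)
write.csv(summaries, "results/screen_well_summaries.csv", row.names = FALSE)

message("median cells/well: ", median(summaries$n_cells),
        " (target ~300); wells: ", nrow(summaries))
message("wrote results/plate_map.csv, screen_well_truth.csv, ",
        "screen_well_summaries.csv")
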