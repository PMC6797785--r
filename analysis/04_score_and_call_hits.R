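#!/usr/bin/env Rscript
# Score the simulated screen: per-class plate matrices, median-polish
# positional correction, robust Z-scores against the sample population, and
# strict |RZ| > 2 hit calling with majority aggregation over replicates.
# Requires 01_simulate_screen.R to have been run.

suppressPackageStartupMessages(library(rushscreen))
stopifnot(file.exists("results/screen_well_summaries.csv"))

layout <- read_plate_map("results/plate_map.csv")
summaries <- read.csv("results/screen_well_summaries.csv")
truth <- read.csv("results/screen_effects_truth.csv")

scores <- score_plates(summaries, layout)
write.csv(scores, "results/rz_scores.csv", row.names = FALSE)

hits <- call_hits(scores)
write.csv(hits, "results/hits_by_class.csv", row.names = FALSE)
hit_list <- attr(hits, "hit_list")
write.csv(hit_list, "results/hit_list.csv", row.names = FALSE)

active <- truth$compound_id[truth$effect_class != "inert"]
er <- hits[hits$class == "ER_retained", ]
called <- er$compound_id[er$hit]
message(sprintf("ER-retained hits: %d called; sensitivity %.2f, FPR %.4f",
                length(called), mean(active %in% called),
                mean(setdiff(truth$compound_id, active) %in% called)))
for (role in c("DMSO", "DMSO_biotin", "BFA_biotin", "NOCO_biotin")) {
  m <- median(scores$rz[scores$control_role == role &
                          scores$class == "ER_retained"])
  message(sprintf("  median ER-retained RZ, %-12s %8.2f", role, m))
}
message("wrote results/rz_scores.csv, hits_by_class.csv, hit_list.csv")
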