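#!/usr/bin/env Rscript
# Train the four-class phenotype classifier from rendered control wells
# (DMSO, DMSO+biotin, BFA+biotin, nocodazole+biotin; ER+Golgi examples
# synthesized from the generator) and evaluate per-class recall on fresh
# ground-truth cells.

suppressPackageStartupMessages(library(rushscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

params <- default_sim_params()
seg <- default_seg_params()

layout <- make_screen_layout(c(2L, 5L), plate = "TR", replicates = 1L)
effects <- assign_screen_effects(
  unique(layout$compound_id[layout$control_role == "sample"]),
  active_fraction = 0, seed = seed)
sim <- simulate_plate(layout, effects, params,
                      seed = derive_seed(seed, "train"), render = TRUE)
feats <- segment_fields(sim$fields, seg)

spec <- training_spec(seed = derive_seed(seed, "model"))
erg <- synthesize_training_cells("ER_plus_Golgi", params, seg, n_wells = 1,
                                 seed = derive_seed(seed, "erg"))
training <- assemble_training_set(feats, layout, spec, erg)
message("training-set class balance:")
print(attr(training, "class_balance"))

model <- train_classifier(training, spec)
message(sprintf("held-out accuracy (stratified 80/20): %.3f",
                model$report$holdout_accuracy))
print(model$report$confusion)

recalls <- vapply(PHENOTYPE_CLASSES, function(ph) {
  s <- simulate_labeled_cells(ph, params,
                              seed = derive_seed(seed, "eval", ph),
                              n_wells = 1)
  f <- segment_fields(s$fields, seg)
  m <- match_cells_to_truth(f, s$cells)
  ok <- m[!is.na(m$true_phenotype) & !m$border, ]
  mean(classify_cells(model, ok) == ph)
}, numeric(1))
rec <- data.frame(phenotype = names(recalls), recall = unname(recalls))
print(rec)
write.csv(rec, "results/classifier_recall.csv", row.names = FALSE)
message("wrote results/classifier_recall.csv")
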