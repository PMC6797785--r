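#!/usr/bin/env Rscript
# Dose-response confirmation analysis: a 50-compound panel with known
# mechanistic families, 8-point 3-fold dilutions from 10 uM in triplicate;
# 4PL fits of the ER-retained and Golgi-disrupted class-fraction curves,
# high-dose collapse detection, family assignment, and a potency-ordering
# series (2 nM / 200 nM / 1 uM bfa_like compounds on a 10-point series
# from 30 uM).

suppressPackageStartupMessages(library(rushscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

params <- default_sim_params()
doses <- dilution_series(1e-5, 8, 3)

panel_fx <- example_family_panel(50, seed = derive_seed(seed, "panel"))
panel <- simulate_dose_panel(panel_fx, doses, 3, params,
                             seed = derive_seed(seed, "panel_sim"))
write.csv(panel, "results/dr_panel.csv", row.names = FALSE)

profiles <- build_profiles(panel)
families <- classify_family(profiles)
families$true_family <- attr(panel_fx, "true_family")[families$compound_id]
write.csv(families, "results/dr_families.csv", row.names = FALSE)

acc <- mean(families$family == families$true_family)
message(sprintf("family assignment accuracy: %.1f%% of %d compounds",
                100 * acc, nrow(families)))
print(table(truth = families$true_family, assigned = families$family))
message(sprintf("high-dose collapse flagged for %d compounds (%d bfa_like)",
                sum(families$high_dose_collapse_flag),
                sum(families$high_dose_collapse_flag &
                      families$true_family == "bfa_like")))

# potency ordering of a BFA-like series
d10 <- dilution_series(3e-5, 10, 3)
series <- list(BFA = compound_effect("bfa_like", 2e-9, 1, 0.95),
               CMP200 = compound_effect("bfa_like", 2e-7, 1, 0.95),
               CMP1000 = compound_effect("bfa_like", 1e-6, 1, 0.95))
pan <- simulate_dose_panel(series, d10, 3, params,
                           seed = derive_seed(seed, "series"))
ic <- vapply(build_profiles(pan), function(x)
  fit_4pl(x$dose, x$er_mean)$ic50, numeric(1))
print(data.frame(compound = names(ic), fitted_ic50_molar = unname(ic)))
message("note: ER-retained-fraction IC50s sit a few-fold above the ",
        "generator EC50s because intermediate doses park part of the ",
        "affected population in the Golgi-disrupted class; the potency ",
        "ORDERING is the readout here")
message("wrote results/dr_panel.csv, dr_families.csv")
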