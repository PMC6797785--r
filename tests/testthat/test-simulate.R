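test_that("render_cell draws the four phenotypes as specified", {
  p <- default_sim_params()
  # Golgi: EGFP maximum lies inside exactly one compact inclusion of
  # plausible area
  sp <- render_cell("Golgi", p, seed = 1)
  expect_equal(sp$n_puncta, 1L)
  comps <- EBImage::bwlabel(sp$inclusion_mask)
  expect_equal(max(comps), 1)
  expect_true(sp$inclusion_mask[which.max(sp$egfp)])
  area <- sum(sp$inclusion_mask)
  r <- p$phenotype_intensity_params$Golgi$inclusion_radius
  expect_gt(area, 0.5 * pi * r^2)
  expect_lt(area, 2 * pi * r^2)
  # ER_retained: no inclusion, but diffuse signal above background
  for (s in c(1, 7, 19)) {
    sp <- render_cell("ER_retained", p, seed = s)
    expect_equal(sum(sp$inclusion_mask), 0)
    expect_gt(max(sp$egfp), 0.1)
  }
  # ER_plus_Golgi carries both components
  sp <- render_cell("ER_plus_Golgi", p, seed = 3)
  expect_gt(sum(sp$inclusion_mask), 0)
  expect_gt(max(sp$egfp * !sp$inclusion_mask), 0.05)
  # Golgi_disrupted: >= 3 puncta; count equals the configured draw (3 + a
  # Poisson deviate), reproduced by identical re-rendering
  sp7 <- render_cell("Golgi_disrupted", p, seed = 7)
  expect_gte(sp7$n_puncta, 3L)
  again <- render_cell("Golgi_disrupted", p, seed = 7)
  expect_identical(sp7$n_puncta, again$n_puncta)
  expect_identical(sp7$egfp, again$egfp)
  expect_error(render_cell("Lysosome", p), "unknown phenotype")
})

test_that("simulate_well mixtures obey the zero, saturating and EC50 limits", {
  p <- default_sim_params()
  # inert compound + biotin: nearly all cells released to the Golgi
  pr <- well_phenotype_probs(compound_effect("inert"), 1e-5, TRUE, p)
  expect_gte(pr[["Golgi"]], 0.95)
  sim <- simulate_well(list(compound = compound_effect("inert"),
                            concentration = 1e-5, biotin = TRUE), p,
                       seed = 2, render = FALSE)
  n <- sim$well$n_cells
  expect_gte(round(sim$well$fractions[["Golgi"]] * n),
             qbinom(0.005, n, pr[["Golgi"]]))
  # saturating bfa_like: nearly all ER-retained
  bfa <- compound_effect("bfa_like", ec50 = 1e-9, hill_slope = 1,
                         max_effect = 1)
  sim <- simulate_well(list(compound = bfa, concentration = 1e-4,
                            biotin = TRUE), p, seed = 3, render = FALSE)
  expect_gte(sim$well$fractions[["ER_retained"]], 0.95)
  # at c = ec50 with hill 1 and max_effect 1 the affected fraction is 0.5:
  # the observed ER count lies within the binomial 99% CI around the
  # expected mixture (gd_weight 0 makes the target purely ER-retained)
  eff <- compound_effect("bfa_like", ec50 = 1e-7, hill_slope = 1,
                         max_effect = 1, gd_weight = 0)
  sim <- simulate_well(list(compound = eff, concentration = 1e-7,
                            biotin = TRUE), p, seed = 4, render = FALSE)
  n <- sim$well$n_cells
  p_er <- 0.5 * 1 + 0.5 * p$baseline_probs_biotin[["ER_retained"]]
  k <- round(sim$well$fractions[["ER_retained"]] * n)
  expect_gte(k, qbinom(0.005, n, p_er))
  expect_lte(k, qbinom(0.995, n, p_er))
  expect_error(simulate_well(list(concentration = -1, biotin = TRUE), p),
               "negative concentration")
})

test_that("phenotype mixtures are calibrated over many wells", {
  # empirical fractions match the specified mixture within 3 binomial SEs,
  # pooled over 50 wells per condition
  p <- default_sim_params()
  conds <- list(
    list(compound = NULL, concentration = 0, biotin = TRUE),
    list(compound = compound_effect("er_retainer", 2e-7, 1.2, 0.9),
         concentration = 2e-7, biotin = TRUE),
    list(compound = compound_effect("mt_depolymerizer_like", 3e-7, 2.5, 0.95),
         concentration = 1e-6, biotin = TRUE)
  )
  for (cond in conds) {
    probs <- well_phenotype_probs(cond$compound, cond$concentration,
                                  cond$biotin, p)
    counts <- stats::setNames(numeric(4), PHENOTYPE_CLASSES)
    n_tot <- 0
    for (w in 1:50) {
      sim <- simulate_well(cond, p, seed = derive_seed(77, "cal", w),
                           render = FALSE)
      counts <- counts + sim$well$fractions * sim$well$n_cells
      n_tot <- n_tot + sim$well$n_cells
    }
    emp <- counts / n_tot
    se <- sqrt(probs * (1 - probs) / n_tot)
    expect_true(all(abs(emp - probs) <= 3 * se + 1e-12))
  }
})

test_that("affected fraction is non-decreasing in concentration", {
  p <- default_sim_params()
  doses <- 10^seq(-10, -4, length.out = 25)
  effects <- list(
    compound_effect("er_retainer", 1e-7, 0.8, 0.7),
    compound_effect("bfa_like", 2e-7, 1.5, 0.9),
    compound_effect("mt_depolymerizer_like", 5e-8, 2.5, 1),
    compound_effect("golgi_disruptor", 1e-6, 1, 0.55)
  )
  for (eff in effects) {
    base <- well_phenotype_probs(NULL, 0, TRUE, p)[["Golgi"]]
    affected <- vapply(doses, function(d) {
      pr <- well_phenotype_probs(eff, d, TRUE, p)
      1 - pr[["Golgi"]] / base
    }, numeric(1))
    expect_true(all(diff(affected) >= -1e-12))
  }
})

test_that("simulate_plate applies the gradient additively and reproducibly", {
  # gradient amplitude 0: per-well true mixtures equal the well marginals
  lay <- make_screen_layout(c(4L, 6L), replicates = 1L)
  ids <- unique(lay$compound_id[lay$control_role == "sample"])
  fx <- assign_screen_effects(ids, active_fraction = 0, seed = 1)
  p0 <- default_sim_params(positional_gradient_amplitude = 0,
                           nuisance_retention_sd = 0)
  sim <- simulate_plate(lay, fx, p0, seed = 9, render = FALSE)
  marg <- well_phenotype_probs(NULL, 0, TRUE, p0)
  smp <- sim$wells[sim$wells$control_role == "sample", ]
  for (cl in PHENOTYPE_CLASSES)
    expect_equal(smp[[paste0("prob_", cl)]], rep(marg[[cl]], nrow(smp)))
  # 16x24 all-sample plate, amplitude 0.1: median polish of the noise-free
  # true fractions recovers the row-effect vector to within 1e-6
  fmt <- c(16L, 24L)
  grid <- expand.grid(row = 1:16, col = 1:24)
  lay2 <- validate_plate_layout(data.frame(
    plate = "G", well = rc_to_well(grid$row, grid$col, fmt),
    compound_id = sprintf("C%03d", seq_len(384)),
    concentration_molar = 1e-5, biotin = 1L, control_role = "sample",
    replicate = 1L), fmt)
  fx2 <- assign_screen_effects(lay2$compound_id, active_fraction = 0, seed = 1)
  p1 <- default_sim_params(positional_gradient_amplitude = 0.1,
                           nuisance_retention_sd = 0)
  sim2 <- simulate_plate(lay2, fx2, p1, seed = 10, render = FALSE)
  m <- matrix(NA_real_, 16, 24)
  m[cbind(sim2$wells$row, sim2$wells$col)] <- sim2$wells$prob_ER_retained
  mp <- median_polish(m, max_iter = 50, tol = 1e-12)
  expect_equal(mp$row_effects - mean(mp$row_effects),
               sim2$gradient$row - mean(sim2$gradient$row), tolerance = 1e-6)
  expect_equal(mp$col_effects - mean(mp$col_effects),
               sim2$gradient$col - mean(sim2$gradient$col), tolerance = 1e-6)
  expect_lt(max(abs(mp$residuals)), 1e-9)
  # duplicate well address rejected
  bad <- rbind(lay, lay[1, ])
  expect_error(simulate_plate(bad, fx, p0, seed = 1), "duplicate")
})

test_that("identical parameters and seed reproduce a plate bit-identically", {
  p <- small_sim_params()
  lay <- make_screen_layout(c(2L, 5L), plate = "D", replicates = 1L)
  fx <- assign_screen_effects(unique(lay$compound_id[lay$control_role ==
                                                       "sample"]),
                              active_fraction = 0, seed = 3)
  s1 <- simulate_plate(lay, fx, p, seed = 33, render = TRUE)
  s2 <- simulate_plate(lay, fx, p, seed = 33, render = TRUE)
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$cells, s2$cells)
  for (i in seq_along(s1$fields))
    expect_identical(s1$fields[[i]]$channels, s2$fields[[i]]$channels)
  # wells are keyed by (seed, plate, well, replicate): a different seed
  # changes the draw
  s3 <- simulate_plate(lay, fx, p, seed = 34, render = FALSE)
  expect_false(identical(s1$wells$n_cells, s3$wells$n_cells))
})

test_that("toxic compounds reduce the cell count instead of the mixture", {
  p <- default_sim_params()
  tox <- compound_effect("toxic", ec50 = 1e-7, hill_slope = 1, max_effect = 0.9)
  sims <- vapply(1:20, function(i)
    simulate_well(list(compound = tox, concentration = 1e-5, biotin = TRUE),
                  p, seed = i, render = FALSE)$well$n_cells, numeric(1))
  expect_lt(mean(sims), 0.25 * p$cells_per_well_mean)
  pr <- well_phenotype_probs(tox, 1e-5, TRUE, p)
  expect_equal(as.numeric(pr), as.numeric(p$baseline_probs_biotin))
})
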