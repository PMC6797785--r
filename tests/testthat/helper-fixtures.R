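# Shared fixtures. Heavy rendered fixtures are built once per test run and
# memoized here; everything is generated in code under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small, fast generator settings for module-level image tests
small_sim_params <- function(...) {
  default_sim_params(field_size_px = 128L, cells_per_well_mean = 50,
                     n_fields_per_well = 2L, ...)
}

# classifier trained from rendered control wells at the screen's default
# imaging conditions, plus per-phenotype ground-truth evaluation cells
trained_model_fixture <- function() {
  memo("trained_model", function() {
    p <- default_sim_params()
    sp <- default_seg_params()
    lay <- make_screen_layout(c(2L, 5L), plate = "TR", replicates = 1L)
    fx <- assign_screen_effects(
      unique(lay$compound_id[lay$control_role == "sample"]),
      active_fraction = 0, seed = 1)
    sim <- simulate_plate(lay, fx, p, seed = 101, render = TRUE)
    feats <- segment_fields(sim$fields, sp)
    spec <- training_spec(seed = 7)
    erg <- synthesize_training_cells("ER_plus_Golgi", p, sp,
                                     n_wells = 1, seed = 55)
    training <- assemble_training_set(feats, lay, spec, erg)
    model <- train_classifier(training, spec)
    eval_cells <- lapply(stats::setNames(nm = PHENOTYPE_CLASSES),
                         function(ph) {
      s <- simulate_labeled_cells(ph, p, seed = derive_seed(999, ph),
                                  n_wells = 1)
      f <- segment_fields(s$fields, sp)
      m <- match_cells_to_truth(f, s$cells)
      m[!is.na(m$true_phenotype) & !m$border, , drop = FALSE]
    })
    list(model = model, training = training, eval_cells = eval_cells,
         layout = lay, features_table = feats)
  })
}

# 20 default-parameter fields of biotin-released wells, rendered, segmented
# and matched to ground truth (segmentation-recovery conditions)
segmentation_recovery_fixture <- function() {
  memo("seg_recovery", function() {
    p <- default_sim_params()
    sp <- default_seg_params()
    fields <- list()
    cells <- list()
    for (w in 1:5) {  # 5 wells x 4 fields = 20 fields
      sim <- simulate_well(list(concentration = 0, biotin = TRUE), p,
                           seed = derive_seed(2024, "segwell", w),
                           render = TRUE)
      wid <- sprintf("W%02d", w)
      for (fd in sim$fields) {
        fd$plate <- "SEG"; fd$well <- wid; fd$replicate <- 1L
        fields[[length(fields) + 1L]] <- fd
      }
      sc <- sim$cells
      sc$plate <- "SEG"; sc$well <- wid; sc$replicate <- 1L
      cells[[w]] <- sc
    }
    truth <- do.call(rbind, cells)
    feats <- segment_fields(fields, sp)
    matched <- match_cells_to_truth(feats, truth)
    truth_counts <- table(paste(truth$well, truth$field))
    seg_counts <- table(factor(paste(feats$well, feats$field),
                               names(truth_counts)))
    list(fields = fields, truth = truth, features = feats,
         matched = matched,
         truth_counts = as.integer(truth_counts),
         seg_counts = as.integer(seg_counts))
  })
}

# label-level screening plate under the criterion conditions: 384 wells x 3
# replicates, 5% bfa_like actives, 10% positional gradient
screen_plate_fixture <- function() {
  memo("screen_plate", function() {
    p <- default_sim_params(positional_gradient_amplitude = 0.1)
    lay <- make_screen_layout(c(16L, 24L), replicates = 3L)
    ids <- unique(lay$compound_id[lay$control_role == "sample"])
    fx <- assign_screen_effects(ids, active_fraction = 0.05, seed = 42)
    sim <- simulate_plate(lay, fx, p, seed = 42, render = FALSE)
    scores <- score_plates(truth_well_summaries(sim), lay)
    hits <- call_hits(scores)
    list(layout = lay, ids = ids, active = attr(fx, "active"),
         sim = sim, scores = scores, hits = hits)
  })
}

expect_no_error <- function(expr) expect_error(expr, NA)
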