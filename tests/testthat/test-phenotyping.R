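# compact separable feature table for classifier mechanics tests
separable_features <- function(n_per_class = 120, sd = 0.02, seed = 1) {
  set.seed(seed)
  centers <- list(
    ER_retained = c(inclusion_area = 0, inclusion_count = 0,
                    inclusion_mean = 0, inclusion_total = 0,
                    collar_mean = 0.30, inclusion_collar_ratio = 0,
                    nucleus_area = 80, collar_area = 260),
    ER_plus_Golgi = c(20, 1, 0.45, 9, 0.22, 2.0, 80, 260),
    Golgi = c(21, 1, 0.55, 11, 0.12, 4.5, 80, 260),
    Golgi_disrupted = c(18, 4, 0.35, 6, 0.13, 2.7, 80, 260)
  )
  feats <- names(centers$ER_retained)
  do.call(rbind, lapply(names(centers), function(cl) {
    m <- matrix(rep(unname(centers[[cl]]), each = n_per_class),
                n_per_class) *
      (1 + matrix(rnorm(n_per_class * 8, 0, sd), n_per_class))
    df <- as.data.frame(m)
    names(df) <- feats
    df$label <- cl
    df
  }))
}

test_that("assemble_training_set labels control wells and validates classes", {
  lay <- make_screen_layout(c(2L, 5L), plate = "TR", replicates = 1L)
  cells <- do.call(rbind, lapply(lay$well, function(w) {
    df <- separable_features(10, seed = derive_seed(1, w))
    df$label <- NULL
    df$plate <- "TR"; df$well <- w; df$replicate <- 1L
    df$border <- rep(c(TRUE, rep(FALSE, 9)), 4)
    df
  }))
  spec <- training_spec(min_training_cells = 5L)
  erg <- separable_features(50, seed = 3)
  erg <- erg[erg$label == "ER_plus_Golgi", ]
  tr <- assemble_training_set(cells, lay, spec, erg)
  bal <- attr(tr, "class_balance")
  # 2x5 layout: 2 DMSO_biotin + 2 BFA_biotin + 2 NOCO + 2 DMSO wells of 40
  # non-border cells each, minus border-flagged rows, plus 50 explicit rows
  expect_equal(sum(bal), 8 * 36 + 50)
  expect_equal(unname(bal[["ER_plus_Golgi"]]), 50)
  # a layout lacking Golgi_disrupted controls names the missing class
  lay2 <- lay[lay$control_role != "NOCO_biotin", ]
  expect_error(assemble_training_set(cells, lay2, spec, erg),
               "Golgi_disrupted")
})

test_that("train_classifier is deterministic, separable and honest on noise", {
  tr <- separable_features(100)
  spec <- training_spec(min_training_cells = 10L, seed = 5)
  model <- train_classifier(tr, spec)
  # perfectly separated features: held-out accuracy 1
  expect_equal(model$report$holdout_accuracy, 1)
  probe <- separable_features(30, seed = 9)
  p1 <- classify_cells(model, probe)
  expect_equal(mean(p1 == probe$label), 1)
  # identical seeds give identical predictions
  model2 <- train_classifier(tr, spec)
  expect_identical(p1, classify_cells(model2, probe))
  # shuffled labels: held-out accuracy near the class prior
  shuf <- tr
  set.seed(6)
  shuf$label <- sample(shuf$label)
  macc <- train_classifier(shuf, spec)$report$holdout_accuracy
  prior <- 0.25
  se <- sqrt(prior * (1 - prior) / (0.2 * nrow(tr)))
  expect_lt(abs(macc - prior), 3 * se + 0.05)
  # degenerate features are dropped with a warning
  tr2 <- tr
  tr2$nucleus_area <- 1
  expect_warning(m3 <- train_classifier(tr2, spec), "zero-variance")
  expect_false("nucleus_area" %in% m3$features)
})

test_that("classify_cells enforces its contract", {
  tr <- separable_features(60)
  model <- train_classifier(tr, training_spec(min_training_cells = 10L))
  expect_identical(classify_cells(model, tr[0, ]), character(0))
  expect_error(classify_cells(model, tr[, c("inclusion_area", "label")]),
               "missing feature")
  # undefined inclusion features are imputed as zero inclusion signal
  probe <- separable_features(10, seed = 2)
  er <- probe[probe$label == "ER_retained", ]
  er$inclusion_mean <- NA_real_
  er$inclusion_collar_ratio <- NA_real_
  expect_true(all(classify_cells(model, er) == "ER_retained"))
})

test_that("classifier trained from rendered control wells recovers phenotypes", {
  fx <- trained_model_fixture()
  recalls <- vapply(PHENOTYPE_CLASSES, function(ph) {
    cells <- fx$eval_cells[[ph]]
    mean(classify_cells(fx$model, cells) == ph)
  }, numeric(1))
  expect_gte(recalls[["ER_retained"]], 0.9)
  expect_gte(recalls[["Golgi"]], 0.9)
  expect_gte(recalls[["Golgi_disrupted"]], 0.9)
  expect_gte(recalls[["ER_plus_Golgi"]], 0.75)
  # cells with zero inclusion area and high diffuse signal read ER-retained
  er <- fx$eval_cells$ER_retained
  er <- er[er$inclusion_area == 0 & er$collar_mean > 0.2, ]
  expect_gt(mean(classify_cells(fx$model, er) == "ER_retained"), 0.95)
})

test_that("summarize_wells computes fractions and flags", {
  mk <- function(n, labels, border = FALSE) {
    df <- separable_features(max(n, 1))[seq_len(n), ]
    df$label <- NULL
    df$plate <- "P"; df$well <- "A01"; df$replicate <- 1L
    df$border <- border
    list(cells = df, labels = labels)
  }
  # 300 cells all Golgi
  x <- mk(300, rep("Golgi", 300))
  sm <- summarize_wells(x$cells, x$labels)
  expect_equal(sm$n_cells, 300L)
  expect_equal(unlist(sm[paste0("frac_", PHENOTYPE_CLASSES)],
                      use.names = FALSE), c(0, 0, 1, 0))
  expect_false(sm$low_count)
  # mixed 150/150 ER/Golgi
  x <- mk(300, rep(c("ER_retained", "Golgi"), each = 150))
  sm <- summarize_wells(x$cells, x$labels)
  expect_equal(unlist(sm[paste0("frac_", PHENOTYPE_CLASSES)],
                      use.names = FALSE), c(0.5, 0, 0.5, 0))
  # empty well (via layout): NA fractions, flagged
  lay <- data.frame(plate = "P", well = c("A01", "A02"), replicate = 1L)
  sm <- summarize_wells(x$cells, x$labels, lay)
  empty <- sm[sm$well == "A02", ]
  expect_equal(empty$n_cells, 0L)
  expect_true(all(is.na(unlist(empty[paste0("frac_", PHENOTYPE_CLASSES)]))))
  expect_true(empty$low_count)
  # fractions invariant to cell ordering
  x <- mk(200, sample(rep(PHENOTYPE_CLASSES, 50)))
  sm1 <- summarize_wells(x$cells, x$labels)
  perm <- sample(seq_len(200))
  sm2 <- summarize_wells(x$cells[perm, ], x$labels[perm])
  expect_equal(sm1, sm2)
})
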