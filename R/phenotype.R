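#' Training specification for the phenotype classifier
#'
#' Maps control roles to class labels: wells without biotin (hook retention)
#' and BFA-treated wells train the ER_retained class, DMSO+biotin wells the
#' Golgi class, and nocodazole+biotin wells the Golgi_disrupted class. The
#' controls cover only three of the four classes; ER_plus_Golgi examples are
#' synthesized from the generator by default (or supplied as an explicit
#' labeled table).
#'
#' @param role_map named character vector `control_role -> class`.
#' @param features feature columns used by the classifier.
#' @param min_training_cells minimum examples required per class.
#' @param num_trees random-forest size.
#' @param synthesize_er_plus_golgi synthesize ER_plus_Golgi training cells
#'   from the generator when no explicit table is given.
#' @param n_synth_wells wells to synthesize per missing class.
#' @param seed integer seed (training and synthesis are deterministic in it).
#' @return list of class `training_spec`.
#' @export
training_spec <- function(role_map = c(DMSO = "ER_retained",
                                       DMSO_biotin = "Golgi",
                                       BFA_biotin = "ER_retained",
                                       NOCO_biotin = "Golgi_disrupted"),
                          features = c("nucleus_area", "collar_area",
                                       "collar_mean", "inclusion_area",
                                       "inclusion_count", "inclusion_mean",
                                       "inclusion_total",
                                       "inclusion_collar_ratio"),
                          min_training_cells = 50L, num_trees = 300L,
                          synthesize_er_plus_golgi = TRUE,
                          n_synth_wells = 1L, seed = 1L) {
  stopifnot(all(role_map %in% PHENOTYPE_CLASSES),
            all(names(role_map) %in% CONTROL_ROLES))
  structure(list(role_map = role_map, features = features,
                 min_training_cells = as.integer(min_training_cells),
                 num_trees = as.integer(num_trees),
                 synthesize_er_plus_golgi = synthesize_er_plus_golgi,
                 n_synth_wells = as.integer(n_synth_wells),
                 seed = as.integer(seed)),
            class = "training_spec")
}

# missing-value policy: cells without inclusions carry 0 inclusion signal
.prepare_features <- function(cell_table, features) {
  missing_cols <- setdiff(features, names(cell_table))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  x <- cell_table[, features, drop = FALSE]
  for (f in c("inclusion_mean", "inclusion_collar_ratio", "inclusion_total")) {
    if (f %in% names(x)) x[[f]][is.na(x[[f]])] <- 0
  }
  x
}

#' Assemble the labeled training set from control wells
#'
#' Cells measured in mapped control wells are labeled per the training spec;
#' border-flagged cells are removed. An optional explicit labeled table (e.g.
#' synthesized ER_plus_Golgi cells with a `label` column) is appended. Every
#' class must reach `min_training_cells` examples.
#'
#' @param cell_table per-cell feature table ([segment_fields()]).
#' @param layout plate layout assigning control roles to wells.
#' @param spec a [training_spec()].
#' @param extra_labeled optional data.frame with the feature columns plus
#'   `label`.
#' @return labeled feature data.frame (`label` column) with attribute
#'   `class_balance`.
#' @export
assemble_training_set <- function(cell_table, layout, spec = training_spec(),
                                  extra_labeled = NULL) {
  key <- paste(layout$plate, layout$well, layout$replicate)
  role_of <- stats::setNames(layout$control_role, key)
  ckey <- paste(cell_table$plate, cell_table$well, cell_table$replicate)
  role <- role_of[ckey]
  lab <- unname(spec$role_map[role])
  keep <- !is.na(lab) & !cell_table$border
  train <- cell_table[keep, , drop = FALSE]
  train$label <- lab[keep]
  cols <- c(spec$features, "label")
  train <- train[, intersect(cols, names(train)), drop = FALSE]
  if (!is.null(extra_labeled)) {
    stopifnot("label" %in% names(extra_labeled),
              all(extra_labeled$label %in% PHENOTYPE_CLASSES))
    train <- rbind(train, extra_labeled[, names(train), drop = FALSE])
  }
  balance <- table(factor(train$label, PHENOTYPE_CLASSES))
  short <- names(balance)[balance < spec$min_training_cells]
  if (length(short))
    stop("insufficient training examples for class(es): ",
         paste(short, collapse = ", "))
  attr(train, "class_balance") <- balance
  train
}

#' Synthesize labeled training cells from the generator
#'
#' Renders pure-phenotype wells, segments them, and returns their measured
#' features carrying the forced label. Used to cover the ER_plus_Golgi class,
#' for which the screen's named controls provide no examples.
#'
#' @param phenotype class to synthesize.
#' @param sim_params generator parameters.
#' @param seg_params segmentation parameters.
#' @param n_wells wells to render.
#' @param seed integer seed.
#' @param features feature columns to keep.
#' @return labeled feature data.frame.
#' @export
synthesize_training_cells <- function(phenotype,
                                      sim_params = default_sim_params(),
                                      seg_params = default_seg_params(),
                                      n_wells = 1L, seed = 1L,
                                      features = training_spec()$features) {
  syn <- simulate_labeled_cells(phenotype, sim_params, seed, n_wells)
  feats <- segment_fields(syn$fields, seg_params)
  feats <- feats[!feats$border, , drop = FALSE]
  out <- feats[, features, drop = FALSE]
  out$label <- phenotype
  out
}

#' Train the phenotype classifier
#'
#' Seed-fixed random-forest classifier over the configured features
#' (a one-shot supervised replacement for interactive machine-learning
#' gating). Zero-variance features are dropped with a warning. The training
#' report contains a held-out confusion matrix from a stratified 80/20 split;
#' the returned model is refit on the full table.
#'
#' @param labeled labeled feature table from [assemble_training_set()].
#' @param spec a [training_spec()].
#' @return object of class `phenotype_model` (model, feature list, class
#'   order, seed, training report).
#' @export
train_classifier <- function(labeled, spec = training_spec()) {
  x <- .prepare_features(labeled, spec$features)
  y <- factor(labeled$label, PHENOTYPE_CLASSES)
  keep <- vapply(x, function(v) stats::var(v) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(names(x)[!keep], collapse = ", "))
    if (!any(keep)) stop("no informative features remain")
    x <- x[, keep, drop = FALSE]
  }
  feats <- names(x)
  set.seed(derive_seed(spec$seed, "split"))
  holdout <- unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1L, round(0.2 * length(idx))))))
  fit_tr <- ranger::ranger(x = x[-holdout, , drop = FALSE], y = y[-holdout],
                           num.trees = spec$num_trees, probability = TRUE,
                           seed = spec$seed, num.threads = 1)
  pr <- predict(fit_tr, x[holdout, , drop = FALSE],
                num.threads = 1)$predictions
  pred_h <- PHENOTYPE_CLASSES[max.col(pr[, PHENOTYPE_CLASSES, drop = FALSE],
                                      ties.method = "first")]
  confusion <- table(truth = y[holdout],
                     predicted = factor(pred_h, PHENOTYPE_CLASSES))
  fit <- ranger::ranger(x = x, y = y, num.trees = spec$num_trees,
                        probability = TRUE, seed = spec$seed, num.threads = 1)
  structure(list(
    fit = fit, features = feats, classes = PHENOTYPE_CLASSES,
    seed = spec$seed,
    report = list(confusion = confusion,
                  holdout_accuracy = sum(diag(confusion)) / sum(confusion),
                  class_balance = as.list(table(y)))
  ), class = "phenotype_model")
}

#' Classify cells with a trained phenotype model
#'
#' Every non-border cell receives exactly one of the four class labels; cells
#' with undefined inclusion features are imputed as carrying zero inclusion
#' signal. Class-probability ties are broken by the fixed class order.
#'
#' @param model a `phenotype_model`.
#' @param cell_table per-cell feature table.
#' @return character vector of class labels (one per row of `cell_table`).
#' @export
classify_cells <- function(model, cell_table) {
  stopifnot(inherits(model, "phenotype_model"))
  if (nrow(cell_table) == 0) return(character(0))
  x <- .prepare_features(cell_table, model$features)
  pr <- predict(model$fit, x, num.threads = 1)$predictions
  model$classes[max.col(pr[, model$classes, drop = FALSE],
                        ties.method = "first")]
}

#' Summarize classified cells per well
#'
#' Phenotype-class fractions over non-border cells, per (plate, well,
#' replicate). Wells below the cell-count floor are flagged `low_count`
#' (excluded from hit calling downstream but still reported — the cell count
#' is the screen's toxicity readout); wells with zero cells carry `NA`
#' fractions.
#'
#' @param cell_table per-cell feature table.
#' @param labels class labels from [classify_cells()] (recycled from
#'   `cell_table$label` if missing).
#' @param layout plate layout (defines the complete well set; wells without
#'   cells are reported empty).
#' @param low_count_floor flagging threshold on the cell count.
#' @return WellSummary data.frame: `plate`, `well`, `replicate`, `n_cells`,
#'   `frac_<class>` columns, `low_count`.
#' @export
summarize_wells <- function(cell_table, labels = NULL, layout = NULL,
                            low_count_floor = 50) {
  if (is.null(labels)) labels <- cell_table$label
  stopifnot(length(labels) == nrow(cell_table))
  keep <- !cell_table$border
  ct <- cell_table[keep, , drop = FALSE]
  labels <- labels[keep]
  key <- data.frame(plate = ct$plate, well = ct$well, replicate = ct$replicate)
  if (!is.null(layout)) {
    all_wells <- unique(data.frame(plate = layout$plate, well = layout$well,
                                   replicate = layout$replicate))
  } else {
    all_wells <- unique(key)
  }
  out <- all_wells
  kstr <- paste(key$plate, key$well, key$replicate)
  ostr <- paste(out$plate, out$well, out$replicate)
  out$n_cells <- as.integer(table(factor(kstr, ostr))[ostr])
  for (cl in PHENOTYPE_CLASSES) out[[paste0("frac_", cl)]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- kstr == ostr[i]
    n <- sum(sel)
    if (n > 0) {
      tab <- table(factor(labels[sel], PHENOTYPE_CLASSES)) / n
      for (cl in PHENOTYPE_CLASSES)
        out[[paste0("frac_", cl)]][i] <- tab[[cl]]
    }
  }
  out$low_count <- out$n_cells < low_count_floor
  rownames(out) <- NULL
  out
}
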