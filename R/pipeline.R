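#' Default pipeline configuration
#'
#' A single nested configuration covering every stage (simulation,
#' segmentation, phenotyping, statistics, dose-response), the global seed,
#' and the plate format. The default values describe a small demonstration
#' screen (24-well plate map, two replicate experiments, two fields per well)
#' that exercises the full pipeline quickly; the screen-scale study conditions
#' are set by the individual stage defaults
#' ([default_sim_params()], [make_screen_layout()]).
#'
#' @param seed global integer seed; fanned out to per-stage, per-well
#'   sub-streams via [derive_seed()].
#' @param ... named overrides of top-level blocks.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    plate_format = c(4L, 6L),
    layout = list(type = "demo", plate = "DEMO", replicates = 2L,
                  screening_dose = 1e-5),
    simulation = list(cells_per_well_mean = 120, n_fields_per_well = 2L,
                      field_size_px = 192L,
                      positional_gradient_amplitude = 0.1),
    screening = list(active_fraction = 0.25, active_ec50 = 2e-7,
                     active_hill = 1, active_max_effect = 0.85),
    segmentation = list(),
    phenotyping = list(min_training_cells = 50L, num_trees = 300L,
                       n_synth_wells = 1L, low_count_floor = 50L),
    stats = list(polish = TRUE, threshold = 2, aggregation = "majority"),
    dose_response = list(enabled = TRUE, n_compounds = 5L,
                         dose_start = 1e-5, n_doses = 8L, dose_fold = 3,
                         n_replicates = 3L),
    log_level = "info"
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config block(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(ov)) {
      if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
        cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
      else cfg[[nm]] <- ov[[nm]]
    }
  }
  cfg
}

#' Write / read a pipeline configuration (YAML)
#'
#' Round-trips losslessly: `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$plate_format <- as.integer(unlist(cfg$plate_format))
  for (f in c("replicates")) cfg$layout[[f]] <- as.integer(cfg$layout[[f]])
  cfg
}

.cfg_layout <- function(config) {
  ly <- config$layout
  if (identical(ly$type, "demo")) {
    make_screen_layout(config$plate_format, plate = ly$plate %||% "DEMO",
                       replicates = ly$replicates %||% 2L,
                       screening_dose = ly$screening_dose %||% 1e-5)
  } else if (!is.null(ly$path)) {
    read_plate_map(ly$path, config$plate_format)
  } else stop("layout config needs type='demo' or a path")
}

.cfg_sim_params <- function(config) {
  do.call(default_sim_params, config$simulation %||% list())
}

.cfg_seg_params <- function(config) {
  do.call(default_seg_params, config$segmentation %||% list())
}

.need <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop("missing upstream output for stage '", stage, "': ", path,
         " (run stage '", produced_by, "' first)")
  path
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the screening pipeline
#'
#' Executes the requested stages in fixed order
#' (simulate -> segment -> classify -> score -> hits -> doseresponse),
#' persisting every stage's outputs under `out_dir` so stages can also be run
#' in separate calls. The resolved configuration is written next to the
#' outputs and a manifest records the stages run, the seed, the package
#' version, and an MD5 hash of every output file. Re-running with identical
#' configuration and seed reproduces identical output tables.
#'
#' @param config configuration list ([default_pipeline_config()]).
#' @param out_dir run directory (created).
#' @param stages subset of stages to run.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         stages = c("simulate", "segment", "classify",
                                    "score", "hits", "doseresponse")) {
  order_all <- c("simulate", "segment", "classify", "score", "hits",
                 "doseresponse")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  seed <- config$seed
  sim_params <- .cfg_sim_params(config)
  seg_params <- .cfg_seg_params(config)
  ran <- character(0)

  if ("simulate" %in% stages) {
    layout <- .cfg_layout(config)
    write_plate_map(layout, file.path(out_dir, "plate_map.csv"))
    ids <- unique(layout$compound_id[layout$control_role == "sample"])
    effects <- assign_screen_effects(
      ids, config$screening$active_fraction,
      compound_effect("bfa_like", ec50 = config$screening$active_ec50,
                      hill_slope = config$screening$active_hill,
                      max_effect = config$screening$active_max_effect),
      seed = seed)
    sim <- simulate_plate(layout, effects, sim_params,
                          seed = derive_seed(seed, "simulate"),
                          render = TRUE)
    write_field_images(sim, file.path(out_dir, "images"))
    .write_csv(sim$cells, file.path(out_dir, "truth_cells.csv"))
    jsonlite::write_json(
      list(wells = sim$wells, effects = sim$effects,
           gradient = sim$gradient, active = attr(effects, "active")),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
    ran <- c(ran, "simulate")
  }

  if ("segment" %in% stages) {
    .need(file.path(out_dir, "images", "manifest.csv"), "segment", "simulate")
    fields <- read_field_images(file.path(out_dir, "images"))
    feats <- segment_fields(fields, seg_params)
    .write_csv(feats, file.path(out_dir, "cell_features.csv"))
    ran <- c(ran, "segment")
  }

  if ("classify" %in% stages) {
    fpath <- .need(file.path(out_dir, "cell_features.csv"), "classify",
                   "segment")
    lpath <- .need(file.path(out_dir, "plate_map.csv"), "classify", "simulate")
    feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
    layout <- read_plate_map(lpath, config$plate_format)
    ph <- config$phenotyping
    spec <- training_spec(min_training_cells = ph$min_training_cells %||% 50L,
                          num_trees = ph$num_trees %||% 300L,
                          n_synth_wells = ph$n_synth_wells %||% 1L,
                          seed = derive_seed(seed, "classify"))
    extra <- if (isTRUE(spec$synthesize_er_plus_golgi))
      synthesize_training_cells("ER_plus_Golgi", sim_params, seg_params,
                                spec$n_synth_wells,
                                derive_seed(seed, "synth_erg"),
                                spec$features)
    else NULL
    training <- assemble_training_set(feats, layout, spec, extra)
    model <- train_classifier(training, spec)
    feats$label <- classify_cells(model, feats)
    .write_csv(feats, file.path(out_dir, "cell_labels.csv"))
    summaries <- summarize_wells(feats, feats$label, layout,
                                 ph$low_count_floor %||% 50)
    .write_csv(summaries, file.path(out_dir, "well_summaries.csv"))
    jsonlite::write_json(
      list(features = model$features, classes = model$classes,
           seed = model$seed,
           holdout_accuracy = model$report$holdout_accuracy,
           confusion = as.data.frame(model$report$confusion),
           class_balance = model$report$class_balance),
      file.path(out_dir, "phenotype_model.json"), digits = NA,
      auto_unbox = TRUE)
    ran <- c(ran, "classify")
  }

  if ("score" %in% stages) {
    spath <- .need(file.path(out_dir, "well_summaries.csv"), "score",
                   "classify")
    lpath <- .need(file.path(out_dir, "plate_map.csv"), "score", "simulate")
    summaries <- utils::read.csv(spath, stringsAsFactors = FALSE)
    layout <- read_plate_map(lpath, config$plate_format)
    scores <- score_plates(summaries, layout,
                           polish = isTRUE(config$stats$polish %||% TRUE))
    .write_csv(scores, file.path(out_dir, "rz_scores.csv"))
    ran <- c(ran, "score")
  }

  if ("hits" %in% stages) {
    rpath <- .need(file.path(out_dir, "rz_scores.csv"), "hits", "score")
    scores <- utils::read.csv(rpath, stringsAsFactors = FALSE)
    hits <- call_hits(scores, threshold = config$stats$threshold %||% 2,
                      aggregation = config$stats$aggregation %||% "majority")
    .write_csv(hits, file.path(out_dir, "hits.csv"))
    .write_csv(attr(hits, "hit_list"), file.path(out_dir, "hit_list.csv"))
    ran <- c(ran, "hits")
  }

  if ("doseresponse" %in% stages && isTRUE(config$dose_response$enabled)) {
    dr <- config$dose_response
    panel_fx <- example_family_panel(dr$n_compounds %||% 5L,
                                     seed = derive_seed(seed, "dr_panel"))
    doses <- dilution_series(dr$dose_start %||% 1e-5, dr$n_doses %||% 8L,
                             dr$dose_fold %||% 3)
    panel <- simulate_dose_panel(panel_fx, doses, dr$n_replicates %||% 3L,
                                 sim_params, derive_seed(seed, "dr"))
    .write_csv(panel, file.path(out_dir, "dr_panel.csv"))
    profiles <- build_profiles(panel)
    curves <- do.call(rbind, lapply(names(profiles), function(id) {
      pr <- profiles[[id]]
      pr$compound_id <- id
      pr
    }))
    .write_csv(curves, file.path(out_dir, "dr_curves.csv"))
    fam <- classify_family(profiles)
    fam$true_family <- attr(panel_fx, "true_family")[fam$compound_id]
    .write_csv(fam, file.path(out_dir, "dr_families.csv"))
    ran <- c(ran, "doseresponse")
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json"))
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    stages = ran, seed = seed,
    package_version = as.character(utils::packageVersion("rushscreen")),
    files = data.frame(file = files, md5 = unname(hashes))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Export a run report
#'
#' Reads the stage outputs of a [run_pipeline()] run directory and writes a
#' machine-readable JSON summary plus a human-readable markdown report:
#' per-class RZ distributions split by control role, the hit table (or an
#' explicit statement that no hits were called), and the dose-response family
#' table when that stage was run.
#'
#' @param run_dir run directory.
#' @return (invisibly) the summary list.
#' @export
export_report <- function(run_dir) {
  rz_path <- file.path(run_dir, "rz_scores.csv")
  if (!file.exists(rz_path))
    stop("scoring stage output not found in ", run_dir)
  scores <- utils::read.csv(rz_path, stringsAsFactors = FALSE)
  rz_summary <- do.call(rbind, lapply(
    split(scores, list(scores$control_role, scores$class), drop = TRUE),
    function(s) data.frame(control_role = s$control_role[1],
                           class = s$class[1], n = nrow(s),
                           median_rz = stats::median(s$rz, na.rm = TRUE),
                           q25 = stats::quantile(s$rz, 0.25, na.rm = TRUE),
                           q75 = stats::quantile(s$rz, 0.75, na.rm = TRUE))))
  rownames(rz_summary) <- NULL

  hit_path <- file.path(run_dir, "hit_list.csv")
  hits <- if (file.exists(hit_path))
    utils::read.csv(hit_path, stringsAsFactors = FALSE)
  else NULL
  fam_path <- file.path(run_dir, "dr_families.csv")
  families <- if (file.exists(fam_path))
    utils::read.csv(fam_path, stringsAsFactors = FALSE)
  else NULL

  summary <- list(rz_by_role = rz_summary,
                  n_hits = if (is.null(hits)) NA_integer_ else nrow(hits),
                  hits = hits, dose_response_families = families)
  jsonlite::write_json(summary, file.path(run_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)

  md <- c("# Screen run report", "",
          "## Per-class RZ-score distributions by control role", "",
          paste(utils::capture.output(print(rz_summary)), collapse = "\n"),
          "", "## Hits", "")
  if (is.null(hits)) {
    md <- c(md, "Hit-calling stage not run.")
  } else if (nrow(hits) == 0) {
    md <- c(md, "Zero hits were called.")
  } else {
    md <- c(md, paste(utils::capture.output(print(hits)), collapse = "\n"))
  }
  if (!is.null(families)) {
    md <- c(md, "", "## Dose-response families", "",
            paste(utils::capture.output(
              print(families[, c("compound_id", "family",
                                 "high_dose_collapse_flag", "er_ic50",
                                 "gd_ic50")])), collapse = "\n"))
  }
  writeLines(md, file.path(run_dir, "report.md"))
  invisible(summary)
}
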