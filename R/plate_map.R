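#' Read and validate a plate-map CSV
#'
#' Expected columns: `plate`, `well` (e.g. `"B03"`), `compound_id`,
#' `concentration_molar`, `biotin` (0/1), `control_role` (one of
#' [CONTROL_ROLES]), `replicate`. Well addresses are validated against the
#' plate format and duplicate (plate, well, replicate) rows are rejected.
#'
#' @param path CSV file path.
#' @param format plate format `c(rows, cols)`.
#' @return a validated `plate_layout` data.frame with added `row`/`col`
#'   indices.
#' @export
read_plate_map <- function(path, format = c(16L, 24L)) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate_layout(df, format, source = path)
}

#' @rdname read_plate_map
#' @param layout a plate-map data.frame.
#' @param source label used in error messages.
#' @export
validate_plate_layout <- function(layout, format = c(16L, 24L),
                                  source = "layout") {
  required <- c("plate", "well", "compound_id", "concentration_molar",
                "biotin", "control_role", "replicate")
  missing_cols <- setdiff(required, names(layout))
  if (length(missing_cols))
    stop(source, ": missing column(s): ", paste(missing_cols, collapse = ", "))

  line <- seq_len(nrow(layout)) + 1L  # header is line 1 in the CSV
  bad_role <- !layout$control_role %in% CONTROL_ROLES
  if (any(bad_role))
    stop(source, ": unknown control_role '",
         layout$control_role[which(bad_role)[1]], "' at line ",
         line[which(bad_role)[1]])

  bad_well <- !grepl("^[A-Z][0-9]{2}$", layout$well)
  if (!any(bad_well)) {
    rr <- match(substr(layout$well, 1, 1), LETTERS)
    cc <- as.integer(substr(layout$well, 2, 3))
    bad_well <- rr > format[1] | cc < 1L | cc > format[2]
  }
  if (any(bad_well))
    stop(source, ": malformed or out-of-bounds well address '",
         layout$well[which(bad_well)[1]], "' at line ", line[which(bad_well)[1]])

  key <- paste(layout$plate, layout$well, layout$replicate)
  if (anyDuplicated(key))
    stop(source, ": duplicate (plate, well, replicate) '",
         key[which(duplicated(key))[1]], "' at line ",
         line[which(duplicated(key))[1]])

  stopifnot(all(layout$concentration_molar >= 0),
            all(layout$biotin %in% c(0L, 1L)))
  rc <- well_to_rc(layout$well, format)
  layout$row <- rc$row
  layout$col <- rc$col
  attr(layout, "format") <- as.integer(format)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Write a plate map to CSV
#' @param layout a `plate_layout` data.frame.
#' @param path output CSV path.
#' @export
write_plate_map <- function(layout, path) {
  cols <- c("plate", "well", "compound_id", "concentration_molar",
            "biotin", "control_role", "replicate")
  utils::write.csv(layout[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a standard screening-plate layout
#'
#' Controls occupy the outer columns: first column DMSO + biotin (neutral),
#' second column BFA + biotin (ER-retained control), next-to-last column
#' nocodazole + biotin (Golgi-disrupted control), last column DMSO without
#' biotin (ER-retained by hook retention). All remaining wells are library
#' samples with biotin, dosed at `screening_dose`.
#'
#' @param format plate format `c(rows, cols)`.
#' @param plate plate identifier.
#' @param replicates number of replicate experiments (same map per replicate).
#' @param screening_dose single screening concentration (molar).
#' @param bfa_dose,noco_dose control doses (molar).
#' @return a `plate_layout` data.frame.
#' @export
make_screen_layout <- function(format = c(16L, 24L), plate = "P1",
                               replicates = 3L, screening_dose = 1e-5,
                               bfa_dose = 1.8e-5, noco_dose = 1e-5) {
  nr <- format[1]; nc <- format[2]
  stopifnot(nc >= 5)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  role <- rep("sample", nrow(grid))
  role[grid$col == 1L] <- "DMSO_biotin"
  role[grid$col == 2L] <- "BFA_biotin"
  role[grid$col == nc - 1L] <- "NOCO_biotin"
  role[grid$col == nc] <- "DMSO"
  compound <- rep(NA_character_, nrow(grid))
  compound[role == "sample"] <- sprintf("C%03d", seq_len(sum(role == "sample")))
  compound[role %in% c("DMSO", "DMSO_biotin")] <- "DMSO"
  compound[role == "BFA_biotin"] <- "BFA"
  compound[role == "NOCO_biotin"] <- "NOCO"
  conc <- rep(0, nrow(grid))
  conc[role == "sample"] <- screening_dose
  conc[role == "BFA_biotin"] <- bfa_dose
  conc[role == "NOCO_biotin"] <- noco_dose
  one <- data.frame(
    plate = plate,
    well = rc_to_well(grid$row, grid$col, format),
    compound_id = compound,
    concentration_molar = conc,
    biotin = as.integer(role != "DMSO"),
    control_role = role
  )
  layout <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    one$replicate <- r
    one
  }))
  validate_plate_layout(layout, format)
}

#' Assign screening effect models to library compounds
#'
#' A fraction of compounds are spiked as bfa_like actives; the remainder are
#' inert.
#'
#' @param compound_ids character vector of sample compound ids.
#' @param active_fraction fraction of actives.
#' @param active_effect effect model given to actives.
#' @param seed integer seed for the active draw.
#' @return named list of [compound_effect()] models, one per compound, with
#'   attribute `active` (character vector of active ids).
#' @export
assign_screen_effects <- function(compound_ids, active_fraction = 0.05,
                                  active_effect = compound_effect(
                                    "bfa_like", ec50 = 2e-7, hill_slope = 1,
                                    max_effect = 0.85),
                                  seed = 1L) {
  compound_ids <- unique(compound_ids)
  n_active <- round(active_fraction * length(compound_ids))
  set.seed(derive_seed(seed, "screen_actives"))
  active <- sort(sample(compound_ids, n_active))
  effects <- lapply(compound_ids, function(id) {
    if (id %in% active) active_effect else compound_effect("inert")
  })
  names(effects) <- compound_ids
  attr(effects, "active") <- active
  effects
}
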