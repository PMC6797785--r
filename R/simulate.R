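#' @import EBImage
NULL

# squared-distance grid from a continuous center (1-based row/col coords)
.dist2 <- function(n, cy, cx) {
  outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+")
}

.disk <- function(n, cy, cx, r) .dist2(n, cy, cx) <= r^2

#' Render one synthetic cell sprite
#'
#' Draws a 3-channel patch (DNA, EGFP cargo, Golgi marker) for one cell of the
#' given phenotype, plus ground-truth masks. The nucleus is an ellipse; the
#' cargo channel carries a diffuse perinuclear component and/or compact
#' flat-intensity inclusions depending on the phenotype; the marker channel
#' mirrors the inclusion geometry. All components are blurred with the PSF at
#' render time (blurring is linear, so per-sprite blurring followed by
#' compositing equals field-level blurring).
#'
#' @param phenotype one of [PHENOTYPE_CLASSES].
#' @param params simulation parameters from [default_sim_params()].
#' @param seed integer seed; identical `(phenotype, params, seed)` yields an
#'   identical sprite.
#' @return list with `dna`, `egfp`, `golgi` patch matrices, `nucleus_mask`,
#'   `inclusion_mask` (half-maximum delineation of the blurred inclusion
#'   component), `inclusion_component` (blurred, inclusion-only image),
#'   `n_puncta`, and `patch_radius`.
#' @export
render_cell <- function(phenotype, params = default_sim_params(), seed = 1L) {
  if (length(phenotype) != 1L || !phenotype %in% PHENOTYPE_CLASSES)
    stop("unknown phenotype: ", paste(phenotype, collapse = ","))
  set.seed(seed)
  R <- 16L
  n <- 2L * R + 1L
  c0 <- R + 1
  np <- params$nucleus
  a <- max(2, stats::rnorm(1, np$radius_mean, np$radius_sd))
  aspect <- 1 + abs(stats::rnorm(1, 0, np$aspect_sd))
  b <- a / aspect
  theta <- stats::runif(1, 0, pi)
  yy <- outer(seq_len(n) - c0, rep(1, n))
  xx <- outer(rep(1, n), seq_len(n) - c0)
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  nucleus_mask <- (u / a)^2 + (v / b)^2 <= 1
  dna_amp <- max(0.1, stats::rnorm(1, np$intensity_mean, np$intensity_sd))
  dna <- nucleus_mask * dna_amp

  pp <- params$phenotype_intensity_params[[phenotype]]
  s_diff <- exp(stats::rnorm(1, 0, params$intensity_cv))
  s_inc <- exp(stats::rnorm(1, 0, params$intensity_cv))

  # diffuse perinuclear-reticular component: broad Gaussian times a smooth
  # multiplicative texture (correlation length > the inclusion top-hat scales)
  diffuse <- matrix(0, n, n)
  if (pp$diffuse_amp > 0) {
    halo <- exp(-.dist2(n, c0, c0) / (2 * pp$diffuse_sigma^2))
    tex <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n),
                          sigma = params$texture_sigma)
    tex <- tex / max(stats::sd(tex), 1e-12)
    diffuse <- pp$diffuse_amp * s_diff * halo *
      pmax(1 + params$texture_amp * tex, 0)
  }

  # compact inclusions: flat-intensity disks
  incl <- matrix(0, n, n)
  n_puncta <- 0L
  if (pp$inclusion_amp > 0) {
    amp <- pp$inclusion_amp * s_inc
    if (phenotype == "Golgi_disrupted") {
      n_puncta <- as.integer(pp$n_puncta_min + stats::rpois(1, pp$n_puncta_lambda))
      for (i in seq_len(n_puncta)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 2, pp$puncta_spread_px)
        incl <- incl + amp * .disk(n, c0 + d * sin(ang), c0 + d * cos(ang),
                                   pp$inclusion_radius)
      }
      incl <- pmin(incl, amp)  # overlapping puncta stay flat
    } else {
      n_puncta <- 1L
      ang <- stats::runif(1, 0, 2 * pi)
      d <- a + 2
      incl <- amp * .disk(n, c0 + d * sin(ang), c0 + d * cos(ang),
                          pp$inclusion_radius)
    }
  }

  # marker channel mirrors the inclusion geometry; ER-retained cells still
  # have a (cargo-free) Golgi rendered at a juxtanuclear position
  marker <- incl
  if (n_puncta == 0L) {
    ang <- stats::runif(1, 0, 2 * pi)
    d <- a + 2
    marker <- 0.5 * s_inc * .disk(n, c0 + d * sin(ang), c0 + d * cos(ang), 2.6)
  }

  sig <- params$psf_sigma_px
  blur <- function(x) if (sig > 0) EBImage::gblur(x, sigma = sig) else x
  incl_b <- blur(incl)
  inclusion_mask <- if (n_puncta > 0L) incl_b >= 0.5 * max(incl_b)
                    else matrix(FALSE, n, n)
  list(dna = blur(dna), egfp = blur(diffuse) + incl_b, golgi = blur(marker),
       nucleus_mask = nucleus_mask, inclusion_mask = inclusion_mask,
       inclusion_component = incl_b, n_puncta = n_puncta, patch_radius = R)
}

# dart-throwing placement with a minimum center spacing; returns continuous
# (y, x) coordinates, possibly fewer than requested if the field saturates
.place_cells <- function(n_cells, size, margin, min_spacing) {
  ys <- xs <- numeric(0)
  attempts <- 0L
  max_attempts <- 80L * max(n_cells, 1L)
  while (length(ys) < n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    y <- stats::runif(1, margin, size - margin)
    x <- stats::runif(1, margin, size - margin)
    if (!length(ys) || min((ys - y)^2 + (xs - x)^2) >= min_spacing^2) {
      ys <- c(ys, y)
      xs <- c(xs, x)
    }
  }
  data.frame(y = ys, x = xs)
}

#' Render one field from a vector of phenotype labels
#'
#' Places cells with a minimum spacing, composites their sprites, applies
#' channel gains and background, records per-cell ground truth on the
#' noiseless image, then adds Gaussian read noise.
#'
#' @param phenotypes character vector of per-cell phenotype labels.
#' @param params simulation parameters.
#' @param seed integer seed for placement, sprites, and noise.
#' @return list with `channels` (named list of `dna`/`egfp`/`golgi` matrices
#'   in `[0, 1]`) and `cells`, a data.frame of ground truth (0-based `x`/`y`
#'   centroids, phenotype, true inclusion area/mean intensity on the noiseless
#'   field, puncta count).
#' @export
render_field <- function(phenotypes, params = default_sim_params(), seed = 1L) {
  set.seed(derive_seed(seed, "place"))
  S <- params$field_size_px
  pos <- .place_cells(length(phenotypes), S, params$margin_px,
                      params$cell_min_spacing_px)
  k <- nrow(pos)
  phenotypes <- phenotypes[seq_len(k)]
  comp <- list(dna = matrix(0, S, S), egfp = matrix(0, S, S),
               golgi = matrix(0, S, S))
  truth <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- render_cell(phenotypes[i], params, derive_seed(seed, "cell", i))
    R <- sp$patch_radius
    cy <- round(pos$y[i]); cx <- round(pos$x[i])
    fy <- max(1L, cy - R):min(S, cy + R)
    fx <- max(1L, cx - R):min(S, cx + R)
    py <- fy - (cy - R) + 1L
    px <- fx - (cx - R) + 1L
    for (ch in names(comp))
      comp[[ch]][fy, fx] <- comp[[ch]][fy, fx] + sp[[ch]][py, px]
    # inclusion-mask pixel indices in field coordinates
    im <- sp$inclusion_mask[py, px, drop = FALSE]
    idx <- which(im)
    incl_idx <- if (length(idx)) {
      ij <- arrayInd(idx, dim(im))
      (fx[ij[, 2]] - 1L) * S + fy[ij[, 1]]
    } else integer(0)
    truth[[i]] <- list(y = cy - 1L, x = cx - 1L, phenotype = phenotypes[i],
                       n_puncta = sp$n_puncta, incl_idx = incl_idx)
  }
  gains <- params$channel_gains
  noiseless <- list(
    dna = comp$dna * gains[["dna"]] + params$background_level,
    egfp = comp$egfp * gains[["egfp"]] + params$background_level,
    golgi = comp$golgi * gains[["golgi"]] + params$background_level
  )
  cells <- data.frame(
    cell = seq_len(k),
    x = vapply(truth, `[[`, numeric(1), "x"),
    y = vapply(truth, `[[`, numeric(1), "y"),
    phenotype = vapply(truth, function(t) as.character(t$phenotype),
                       character(1)),
    n_puncta = vapply(truth, `[[`, integer(1), "n_puncta"),
    true_inclusion_area = vapply(truth, function(t) length(t$incl_idx),
                                 numeric(1)),
    true_inclusion_mean = vapply(truth, function(t) {
      if (length(t$incl_idx)) mean(noiseless$egfp[t$incl_idx]) else NA_real_
    }, numeric(1))
  )
  set.seed(derive_seed(seed, "noise"))
  channels <- lapply(noiseless, function(ch)
    clamp01(ch + stats::rnorm(length(ch), 0, params$read_noise_sd)))
  list(channels = channels, cells = cells)
}

#' Phenotype mixture of a well under a compound condition
#'
#' Baseline mixture (biotin released: Golgi; no biotin: ER-retained) shifted
#' toward the compound's effect phenotype with probability
#' `max_effect * Hill(conc)`. An additive well-level ER-retention bias
#' (positional gradient and/or compound nuisance) moves probability mass from
#' the baseline majority class into ER_retained.
#'
#' @param effect a [compound_effect()] or `NULL`.
#' @param concentration molar concentration (>= 0).
#' @param biotin logical; was the cargo released?
#' @param params simulation parameters.
#' @param er_bias additive ER-retained probability bias.
#' @return named probability vector over [PHENOTYPE_CLASSES] with attribute
#'   `tox_factor` (multiplier on the expected cell count).
#' @export
well_phenotype_probs <- function(effect = NULL, concentration = 0,
                                 biotin = TRUE,
                                 params = default_sim_params(),
                                 er_bias = 0) {
  if (concentration < 0) stop("concentration must be >= 0")
  base <- if (biotin) params$baseline_probs_biotin
          else params$baseline_probs_no_biotin
  base <- base[PHENOTYPE_CLASSES]
  probs <- base
  tox <- 1
  if (!is.null(effect) && effect$effect_class != "inert") {
    h <- hill_fraction(concentration, effect$ec50, effect$hill_slope)
    if (effect$effect_class == "toxic") {
      tox <- 1 - effect$max_effect * h
    } else {
      p_aff <- effect$max_effect * h
      target <- c(ER_retained = 0, ER_plus_Golgi = 0, Golgi = 0,
                  Golgi_disrupted = 0)
      target[switch(effect$effect_class,
                    er_retainer = "ER_retained",
                    golgi_disruptor = "Golgi_disrupted",
                    mt_depolymerizer_like = "Golgi_disrupted",
                    bfa_like = "ER_retained")] <- 1
      if (effect$effect_class == "bfa_like") {
        gd <- effect$gd_weight * 4 * h * (1 - h)
        target["ER_retained"] <- 1 - gd
        target["Golgi_disrupted"] <- gd
      }
      probs <- (1 - p_aff) * base + p_aff * target
    }
    if (!is.null(effect$toxicity_ec50))
      tox <- tox * (1 - hill_fraction(concentration, effect$toxicity_ec50, 1))
  }
  if (er_bias != 0) {
    donor <- names(base)[which.max(base)]
    probs["ER_retained"] <- probs["ER_retained"] + er_bias
    probs[donor] <- probs[donor] - er_bias
    probs <- pmax(probs, 0)
    probs <- probs / sum(probs)
  }
  structure(probs, tox_factor = tox)
}

#' Simulate one well
#'
#' Draws the well cell count from a Poisson distribution (scaled down by any
#' toxicity), draws per-cell phenotypes from the condition's mixture, splits
#' cells over fields, and (optionally) renders the field images.
#'
#' @param condition list with elements `compound` (a [compound_effect()] or
#'   `NULL`), `concentration`, `biotin`, and optionally `control_role`.
#' @param params simulation parameters.
#' @param seed integer seed; the same inputs reproduce the well exactly.
#' @param render if `FALSE`, only phenotype labels and well-level truth are
#'   produced (no images).
#' @param er_bias additive ER-retention bias (see [well_phenotype_probs()]).
#' @param probs_override optional explicit phenotype probability vector
#'   (bypasses the mixture model; used e.g. to synthesize pure-phenotype
#'   training wells).
#' @return list with `fields` (list of per-field `channels` + truth, when
#'   rendered), `cells` (per-cell truth data.frame), and `well` (list with
#'   `n_cells`, `probs`, realized `fractions`, `er_bias`).
#' @export
simulate_well <- function(condition, params = default_sim_params(), seed = 1L,
                          render = TRUE, er_bias = 0, probs_override = NULL) {
  conc <- condition$concentration %||% 0
  if (conc < 0) stop("negative concentration rejected")
  biotin <- isTRUE(condition$biotin) || identical(condition$biotin, 1L) ||
    identical(condition$biotin, 1)
  probs <- probs_override %||%
    well_phenotype_probs(condition$compound, conc, biotin, params, er_bias)
  tox <- attr(probs, "tox_factor") %||% 1
  probs <- probs[PHENOTYPE_CLASSES]

  set.seed(derive_seed(seed, "count"))
  n_total <- stats::rpois(1, params$cells_per_well_mean * max(tox, 0))
  labels <- if (n_total > 0)
    sample(PHENOTYPE_CLASSES, n_total, replace = TRUE, prob = probs)
  else character(0)
  nf <- params$n_fields_per_well
  field_of <- if (n_total > 0) sample(rep_len(seq_len(nf), n_total))
              else integer(0)

  fields <- vector("list", nf)
  cells <- vector("list", nf)
  for (f in seq_len(nf)) {
    lab_f <- labels[field_of == f]
    if (render) {
      rf <- render_field(lab_f, params, derive_seed(seed, "field", f))
      rf$cells$field <- f
      fields[[f]] <- list(channels = rf$channels, field = f)
      cells[[f]] <- rf$cells
    } else if (length(lab_f)) {
      cells[[f]] <- data.frame(cell = seq_along(lab_f), x = NA_real_,
                               y = NA_real_, phenotype = lab_f,
                               n_puncta = NA_integer_,
                               true_inclusion_area = NA_real_,
                               true_inclusion_mean = NA_real_, field = f)
    }
  }
  cells <- do.call(rbind, cells[!vapply(cells, is.null, logical(1))])
  n_placed <- if (is.null(cells)) 0L else nrow(cells)
  frac <- if (n_placed > 0)
    as.numeric(table(factor(cells$phenotype, PHENOTYPE_CLASSES))) / n_placed
  else rep(NA_real_, 4)
  names(frac) <- PHENOTYPE_CLASSES
  list(fields = if (render) fields else NULL, cells = cells,
       well = list(n_cells = n_placed, probs = probs, fractions = frac,
                   er_bias = er_bias))
}

#' Additive row+column positional gradient
#'
#' One-signed linear ramps over rows and columns (0 at the first row/column,
#' rising toward the last), each spanning half the amplitude, modelling an
#' edge-correlated bias in biotin-release efficiency. Applied additively to
#' the ER-retained class probability of biotin wells; one-signed so that class
#' probabilities need no clipping and the bias stays exactly additive, which
#' is the structure median polish removes.
#'
#' @param format plate format `c(rows, cols)`.
#' @param amplitude total gradient amplitude (maximal row+column bias).
#' @return list with `row` and `col` bias vectors.
#' @export
positional_gradient <- function(format, amplitude) {
  nr <- format[1]; nc <- format[2]
  row <- if (nr > 1) amplitude * 0.5 * (seq_len(nr) - 1) / (nr - 1)
         else rep(0, nr)
  col <- if (nc > 1) amplitude * 0.5 * (seq_len(nc) - 1) / (nc - 1)
         else rep(0, nc)
  list(row = row, col = col)
}

.control_effect_for <- function(role, effects_controls) {
  switch(role,
         BFA = , BFA_biotin = effects_controls$BFA,
         NOCO = , NOCO_biotin = effects_controls$NOCO,
         NULL)
}

#' Simulate a plate (optionally with images)
#'
#' Runs [simulate_well()] for every layout row with per-well RNG sub-streams
#' keyed by `(seed, plate, well, replicate)` (wells are independent and
#' order-insensitive), applies the positional gradient and per-compound
#' nuisance-retention biases at the well level, and collects ground truth.
#'
#' @param layout a `plate_layout` (see [read_plate_map()]); may span several
#'   replicates.
#' @param effects named list of [compound_effect()] models for every sample
#'   compound (see [assign_screen_effects()]).
#' @param params simulation parameters.
#' @param seed master integer seed.
#' @param render render field images (`TRUE`) or produce label-level truth
#'   only (`FALSE`).
#' @param control_effects effect models of the BFA/nocodazole controls.
#' @return object of class `plate_simulation`: list with `wells` (well-level
#'   truth data.frame), `cells` (per-cell truth, when rendered), `fields`
#'   (list of rendered fields with provenance), `gradient`, `effects`,
#'   `layout`, `params`, `seed`.
#' @export
simulate_plate <- function(layout, effects = list(),
                           params = default_sim_params(), seed = 1L,
                           render = FALSE,
                           control_effects = default_control_effects()) {
  layout <- validate_plate_layout(as.data.frame(layout),
                                  attr(layout, "format") %||% c(16L, 24L))
  format <- attr(layout, "format")
  is_sample <- layout$control_role == "sample"
  missing_fx <- setdiff(unique(layout$compound_id[is_sample]), names(effects))
  if (length(missing_fx))
    stop("no effect model for compound(s): ",
         paste(missing_fx, collapse = ", "))

  grad <- positional_gradient(format, params$positional_gradient_amplitude)
  sample_ids <- unique(layout$compound_id[is_sample])
  nuisance <- vapply(sample_ids, function(id) {
    set.seed(derive_seed(seed, "nuisance", id))
    abs(stats::rnorm(1, 0, params$nuisance_retention_sd))
  }, numeric(1))

  wells <- vector("list", nrow(layout))
  cells <- vector("list", nrow(layout))
  fields <- list()
  for (i in seq_len(nrow(layout))) {
    lr <- layout[i, ]
    effect <- if (lr$control_role == "sample") effects[[lr$compound_id]]
              else .control_effect_for(lr$control_role, control_effects)
    biotin <- lr$biotin == 1L
    bias <- if (biotin) {
      grad$row[lr$row] + grad$col[lr$col] +
        (if (lr$control_role == "sample") nuisance[[lr$compound_id]] else 0)
    } else 0
    wseed <- derive_seed(seed, lr$plate, lr$well, lr$replicate)
    sim <- simulate_well(list(compound = effect,
                              concentration = lr$concentration_molar,
                              biotin = biotin),
                         params, wseed, render = render, er_bias = bias)
    w <- data.frame(plate = lr$plate, well = lr$well, replicate = lr$replicate,
                    row = lr$row, col = lr$col,
                    compound_id = lr$compound_id,
                    control_role = lr$control_role,
                    n_cells = sim$well$n_cells, er_bias = bias)
    for (cl in PHENOTYPE_CLASSES) {
      w[[paste0("frac_", cl)]] <- sim$well$fractions[[cl]]
      w[[paste0("prob_", cl)]] <- unname(sim$well$probs[[cl]])
    }
    wells[[i]] <- w
    if (!is.null(sim$cells)) {
      sc <- sim$cells
      sc$plate <- lr$plate; sc$well <- lr$well; sc$replicate <- lr$replicate
      cells[[i]] <- sc
    }
    if (render) {
      for (fd in sim$fields) {
        fd$plate <- lr$plate; fd$well <- lr$well; fd$replicate <- lr$replicate
        fields[[length(fields) + 1L]] <- fd
      }
    }
  }
  effects_summary <- if (length(sample_ids)) data.frame(
    compound_id = sample_ids,
    effect_class = vapply(sample_ids, function(id)
      effects[[id]]$effect_class, character(1)),
    ec50 = vapply(sample_ids, function(id) effects[[id]]$ec50, numeric(1)),
    max_effect = vapply(sample_ids, function(id)
      effects[[id]]$max_effect, numeric(1)),
    nuisance = unname(nuisance)
  ) else NULL
  structure(list(
    wells = do.call(rbind, wells),
    cells = do.call(rbind, cells[!vapply(cells, is.null, logical(1))]),
    fields = if (render) fields else NULL,
    gradient = grad, effects = effects_summary,
    layout = layout, params = params, seed = seed
  ), class = "plate_simulation")
}

#' Well summaries from simulation ground truth
#'
#' Converts the realized per-well phenotype fractions of a
#' [simulate_plate()] run into the WellSummary table consumed by
#' [score_plates()] — the label-level path that bypasses imaging and
#' classification.
#'
#' @param sim a `plate_simulation`.
#' @param low_count_floor wells with fewer cells are flagged (and excluded
#'   from hit calling downstream).
#' @return a WellSummary data.frame.
#' @export
truth_well_summaries <- function(sim, low_count_floor = 50) {
  w <- sim$wells
  out <- w[, c("plate", "well", "replicate", "n_cells",
               paste0("frac_", PHENOTYPE_CLASSES))]
  out$low_count <- out$n_cells < low_count_floor
  out
}

#' Synthesize pure-phenotype cells for training or evaluation
#'
#' Renders wells whose cells all carry one forced phenotype label.
#'
#' @param phenotype one of [PHENOTYPE_CLASSES].
#' @param params simulation parameters.
#' @param seed integer seed.
#' @param n_wells number of wells to render.
#' @return list with `fields` and per-cell ground-truth `cells` (with a
#'   `well` column `SYN1`, `SYN2`, ...).
#' @export
simulate_labeled_cells <- function(phenotype, params = default_sim_params(),
                                   seed = 1L, n_wells = 1L) {
  stopifnot(phenotype %in% PHENOTYPE_CLASSES)
  probs <- stats::setNames(as.numeric(PHENOTYPE_CLASSES == phenotype),
                           PHENOTYPE_CLASSES)
  fields <- list()
  cells <- list()
  for (wl in seq_len(n_wells)) {
    sim <- simulate_well(list(concentration = 0, biotin = TRUE), params,
                         derive_seed(seed, "synth", phenotype, wl),
                         render = TRUE, probs_override = probs)
    wid <- paste0("SYN", wl)
    for (fd in sim$fields) {
      fd$plate <- "SYNTH"; fd$well <- wid; fd$replicate <- 1L
      fields[[length(fields) + 1L]] <- fd
    }
    sc <- sim$cells
    sc$plate <- "SYNTH"; sc$well <- wid; sc$replicate <- 1L
    cells[[wl]] <- sc
  }
  list(fields = fields, cells = do.call(rbind, cells))
}

#' Write rendered fields as TIFF images
#'
#' One single-plane 16-bit TIFF per channel, named
#' `<plate>_<well>_<field>_<channel>.tif` inside a `rep<k>` subdirectory, plus
#' a `manifest.csv` mapping files to (plate, well, field, channel, replicate).
#'
#' @param sim a rendered `plate_simulation` (or any list of field objects
#'   under `$fields`).
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_field_images <- function(sim, dir) {
  stopifnot(!is.null(sim$fields))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (fd in sim$fields) {
    sub <- file.path(dir, paste0("rep", fd$replicate))
    dir.create(sub, showWarnings = FALSE)
    for (ch in names(fd$channels)) {
      fn <- sprintf("%s_%s_%d_%s.tif", fd$plate, fd$well, fd$field, ch)
      tiff::writeTIFF(clamp01(fd$channels[[ch]]), file.path(sub, fn),
                      bits.per.sample = 16L)
      rows[[length(rows) + 1L]] <- data.frame(
        file = file.path(paste0("rep", fd$replicate), fn),
        plate = fd$plate, well = fd$well, field = fd$field,
        channel = ch, replicate = fd$replicate)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  path
}

#' Read fields back from a TIFF image directory
#'
#' @param dir directory containing `manifest.csv` as written by
#'   [write_field_images()].
#' @return list of field objects (`channels`, `plate`, `well`, `field`,
#'   `replicate`).
#' @export
read_field_images <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  key <- unique(manifest[, c("plate", "well", "field", "replicate")])
  lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sel <- manifest[manifest$plate == k$plate & manifest$well == k$well &
                    manifest$field == k$field &
                    manifest$replicate == k$replicate, ]
    channels <- lapply(stats::setNames(sel$file, sel$channel), function(f)
      tiff::readTIFF(file.path(dir, f)))
    list(channels = channels[c("dna", "egfp", "golgi")], plate = k$plate,
         well = k$well, field = k$field, replicate = k$replicate)
  })
}
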