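#' Default synthetic-screen simulation parameters
#'
#' Parameters of the synthetic plate-image generator. Defaults emulate the
#' screen's acquisition statistics: about 300 measurable cells per well imaged
#' in 4 fields, three co-registered channels (DNA, EGFP cargo, Golgi marker),
#' moderate widefield PSF blur and additive read noise, and an optional
#' additive row+column positional bias at the well level.
#'
#' Phenotype appearance models (per class):
#' \describe{
#'   \item{ER_retained}{diffuse perinuclear signal, no compact inclusion.}
#'   \item{ER_plus_Golgi}{reduced diffuse signal plus one dimmer juxtanuclear
#'     inclusion.}
#'   \item{Golgi}{one bright compact juxtanuclear inclusion, faint diffuse
#'     background.}
#'   \item{Golgi_disrupted}{at least 3 small scattered puncta.}
#' }
#' Inclusions are rendered as flat-intensity disks (smoothed by the PSF) so
#' that the mean intensity inside an inclusion is a well-defined ground-truth
#' quantity.
#'
#' @param ... named overrides of any default (nested lists are replaced
#'   wholesale).
#' @return a list of class `sim_params`.
#' @export
default_sim_params <- function(...) {
  p <- list(
    cells_per_well_mean = 300,
    n_fields_per_well = 4L,
    field_size_px = 256L,
    margin_px = 12,
    cell_min_spacing_px = 14,
    channel_gains = c(dna = 1, egfp = 1, golgi = 0.8),
    psf_sigma_px = 0.8,
    read_noise_sd = 0.01,
    background_level = 0.05,
    positional_gradient_amplitude = 0,
    nuisance_retention_sd = 0.005,
    # baseline phenotype mixtures (noise floor of the assay)
    baseline_probs_biotin = c(ER_retained = 0.01, ER_plus_Golgi = 0.02,
                              Golgi = 0.96, Golgi_disrupted = 0.01),
    baseline_probs_no_biotin = c(ER_retained = 0.96, ER_plus_Golgi = 0.02,
                                 Golgi = 0.01, Golgi_disrupted = 0.01),
    nucleus = list(radius_mean = 5.2, radius_sd = 0.4, aspect_sd = 0.12,
                   intensity_mean = 0.55, intensity_sd = 0.05),
    phenotype_intensity_params = list(
      ER_retained = list(diffuse_amp = 0.35, diffuse_sigma = 7,
                         inclusion_amp = 0, inclusion_radius = 0),
      ER_plus_Golgi = list(diffuse_amp = 0.22, diffuse_sigma = 7,
                           inclusion_amp = 0.35, inclusion_radius = 2.6),
      Golgi = list(diffuse_amp = 0.06, diffuse_sigma = 7,
                   inclusion_amp = 0.5, inclusion_radius = 2.6),
      Golgi_disrupted = list(diffuse_amp = 0.08, diffuse_sigma = 7,
                             inclusion_amp = 0.35, inclusion_radius = 1.3,
                             n_puncta_min = 3, n_puncta_lambda = 2,
                             puncta_spread_px = 9)
    ),
    texture_amp = 0.15,
    texture_sigma = 4,
    intensity_cv = 0.12,       # per-cell lognormal amplitude variation
    # well-level mean-inclusion-intensity weights used for the label-level
    # Golgi-signal readout (relative units, matched to the image model)
    golgi_signal_weights = c(ER_retained = 0.02, ER_plus_Golgi = 0.8,
                             Golgi = 1, Golgi_disrupted = 0.45),
    golgi_signal_noise_sd = 0.01,
    rng_seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown simulation parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(
    p$cells_per_well_mean > 0,
    p$field_size_px >= 64,
    p$n_fields_per_well >= 1,
    p$psf_sigma_px >= 0,
    p$read_noise_sd >= 0,
    p$background_level >= 0,
    all(p$channel_gains >= 0),
    p$positional_gradient_amplitude >= 0
  )
  for (ph in names(p$phenotype_intensity_params)) {
    q <- p$phenotype_intensity_params[[ph]]
    if (q$diffuse_amp < 0 || q$inclusion_amp < 0)
      stop("intensity parameters must be >= 0 (phenotype ", ph, ")")
  }
  for (b in list(p$baseline_probs_biotin, p$baseline_probs_no_biotin)) {
    stopifnot(setequal(names(b), PHENOTYPE_CLASSES), all(b >= 0),
              abs(sum(b) - 1) < 1e-9)
  }
  invisible(p)
}

#' Compound dose-effect model
#'
#' Describes what a compound does to the phenotype mixture of a well as a
#' function of concentration. The affected fraction of cells follows a Hill
#' curve `max_effect / (1 + (ec50/c)^hill_slope)`.
#'
#' Effect classes:
#' \describe{
#'   \item{inert}{no effect.}
#'   \item{er_retainer}{affected cells become ER_retained (trafficking block
#'     without Golgi disassembly).}
#'   \item{golgi_disruptor}{affected cells become Golgi_disrupted; shallow
#'     partial response (microtubule destabilizer-like).}
#'   \item{mt_depolymerizer_like}{affected cells become Golgi_disrupted;
#'     steep, near-complete response (nocodazole-like).}
#'   \item{bfa_like}{couples ER retention and Golgi disruption on the same
#'     concentration range: affected cells split between ER_retained and
#'     Golgi_disrupted, the disrupted share being bell-shaped in dose
#'     (`gd_weight * 4 h (1-h)`, h the Hill fraction) so that at saturating
#'     dose the Golgi is fully disassembled and cells are purely ER-retained.}
#'   \item{toxic}{reduces the well cell count by the Hill fraction instead of
#'     shifting phenotypes.}
#' }
#'
#' @param effect_class one of the classes above.
#' @param ec50 half-maximal concentration (molar, > 0).
#' @param hill_slope Hill coefficient (> 0).
#' @param max_effect maximal affected fraction, in `[0, 1]`.
#' @param gd_weight bfa_like only: peak weight of the Golgi-disrupted share.
#' @param toxicity_ec50 optional additional cell-count toxicity EC50 (molar).
#' @return a list of class `compound_effect`.
#' @export
compound_effect <- function(effect_class = c("inert", "er_retainer",
                                             "golgi_disruptor",
                                             "mt_depolymerizer_like",
                                             "bfa_like", "toxic"),
                            ec50 = 1e-6, hill_slope = 1, max_effect = 1,
                            gd_weight = 0.6, toxicity_ec50 = NULL) {
  effect_class <- match.arg(effect_class)
  stopifnot(ec50 > 0, hill_slope > 0, max_effect >= 0, max_effect <= 1,
            gd_weight >= 0, gd_weight <= 1)
  if (!is.null(toxicity_ec50)) stopifnot(toxicity_ec50 > 0)
  structure(list(effect_class = effect_class, ec50 = ec50,
                 hill_slope = hill_slope, max_effect = max_effect,
                 gd_weight = gd_weight, toxicity_ec50 = toxicity_ec50),
            class = "compound_effect")
}

#' Hill occupancy fraction
#'
#' @param conc concentration vector (molar, >= 0).
#' @param ec50,hill_slope Hill parameters.
#' @return fraction in `[0, 1)`; 0 at zero concentration.
#' @export
hill_fraction <- function(conc, ec50, hill_slope = 1) {
  stopifnot(all(conc >= 0), ec50 > 0)
  ifelse(conc <= 0, 0, 1 / (1 + (ec50 / conc)^hill_slope))
}

#' Effect models of the screen's control compounds
#'
#' BFA at the control dose saturates its curve and yields a pure ER-retained
#' phenotype; nocodazole fully scatters the Golgi into puncta.
#'
#' @return named list of [compound_effect()] models for `"BFA"` and `"NOCO"`.
#' @export
default_control_effects <- function() {
  list(
    BFA = compound_effect("bfa_like", ec50 = 2e-9, hill_slope = 1.2,
                          max_effect = 0.99, gd_weight = 0.6),
    NOCO = compound_effect("mt_depolymerizer_like", ec50 = 3e-7,
                           hill_slope = 2.5, max_effect = 0.97)
  )
}
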