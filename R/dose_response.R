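#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r(c) = bottom + (top - bottom) / (1 + (ic50/c)^hill)`
#' on log10 concentration, using Levenberg-Marquardt with multi-start
#' initialization (an IC50 grid spanning the tested range crossed with
#' shallow/steep Hill starts). Non-convergence is reported, never silently
#' returned; an all-equal response vector yields a flat-fit flag.
#'
#' @param concentrations dose vector (molar, > 0, >= 4 distinct values).
#' @param responses response vector (same length).
#' @param weights optional least-squares weights.
#' @return list with `bottom`, `top`, `ic50`, `hill`, `converged`, `flat`,
#'   `rmse`, `n`.
#' @export
fit_4pl <- function(concentrations, responses, weights = NULL) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0))
  if (length(unique(concentrations)) < 4)
    stop("at least 4 distinct concentrations required")
  if (length(unique(responses)) == 1L)
    return(list(bottom = responses[1], top = responses[1], ic50 = NA_real_,
                hill = NA_real_, converged = FALSE, flat = TRUE,
                rmse = 0, n = length(responses)))
  l <- log10(concentrations)
  if (is.null(weights)) weights <- rep(1, length(responses))
  lo <- c(bottom = -Inf, top = -Inf, l50 = min(l) - 3, hill = 0.05)
  hi <- c(bottom = Inf, top = Inf, l50 = max(l) + 3, hill = 10)
  starts <- expand.grid(
    l50 = stats::quantile(l, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE),
    hill = c(0.8, 2.5)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) /
          (1 + 10^(hill * (l50 - l))),
        start = list(bottom = min(responses), top = max(responses),
                     l50 = starts$l50[i], hill = starts$hill[i]),
        lower = lo, upper = hi, weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(weights * stats::residuals(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best))
    return(list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, converged = FALSE, flat = FALSE,
                rmse = NA_real_, n = length(responses)))
  cf <- stats::coef(best$fit)
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       ic50 = unname(10^cf["l50"]), hill = unname(cf["hill"]),
       converged = TRUE, flat = FALSE,
       rmse = sqrt(best$dev / sum(weights)), n = length(responses))
}

#' Evaluate a fitted 4PL curve
#' @param fit result of [fit_4pl()].
#' @param concentrations doses (molar, > 0).
#' @return predicted responses.
#' @export
predict_4pl <- function(fit, concentrations) {
  fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$ic50 / concentrations)^fit$hill)
}

#' Simulate a dose-response panel at the well-summary level
#'
#' For each compound, dose and replicate, draws the well cell count and the
#' multinomial phenotype composition from the generator's mixture model, plus
#' the well-level Golgi-signal readout (ground-truth mean inclusion intensity,
#' a class-weighted average with additive noise).
#'
#' @param compounds named list of [compound_effect()] models.
#' @param doses concentration vector (molar).
#' @param n_replicates replicates per dose.
#' @param params simulation parameters.
#' @param seed master seed.
#' @return data.frame: compound_id, concentration_molar, replicate, n_cells,
#'   `frac_<class>` columns, golgi_signal.
#' @export
simulate_dose_panel <- function(compounds, doses, n_replicates = 3L,
                                params = default_sim_params(), seed = 1L) {
  stopifnot(length(names(compounds)) == length(compounds))
  rows <- list()
  w <- params$golgi_signal_weights[PHENOTYPE_CLASSES]
  for (id in names(compounds)) {
    for (d in doses) {
      for (r in seq_len(n_replicates)) {
        set.seed(derive_seed(seed, "panel", id, signif(d, 8), r))
        probs <- well_phenotype_probs(compounds[[id]], d, biotin = TRUE,
                                      params = params)
        tox <- attr(probs, "tox_factor")
        n <- stats::rpois(1, params$cells_per_well_mean * max(tox, 0))
        frac <- if (n > 0) as.numeric(stats::rmultinom(1, n, probs)) / n
                else rep(NA_real_, 4)
        gs <- if (n > 0)
          sum(frac * w) + stats::rnorm(1, 0, params$golgi_signal_noise_sd)
        else NA_real_
        row <- data.frame(compound_id = id, concentration_molar = d,
                          replicate = r, n_cells = n, golgi_signal = gs)
        for (k in seq_along(PHENOTYPE_CLASSES))
          row[[paste0("frac_", PHENOTYPE_CLASSES[k])]] <- frac[k]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Build per-compound dose-response profiles
#'
#' Averages replicate responses per dose (with SDs and replicate counts,
#' flagging doses with missing replicates), orders doses ascending, and
#' carries the ER-retained and Golgi-disrupted class-fraction curves together
#' with the Golgi-signal curve used for collapse detection. Compounds with a
#' single dose are excluded with a warning.
#'
#' @param panel long table as from [simulate_dose_panel()] (or a merged
#'   WellSummary + layout table with `compound_id`, `concentration_molar`,
#'   `replicate`, `frac_*`, and optionally `golgi_signal` columns).
#' @return named list of `dose_profile` data.frames (`dose`, `er_mean`,
#'   `er_sd`, `gd_mean`, `gd_sd`, `gs_mean`, `n_rep`, `incomplete`).
#' @export
build_profiles <- function(panel) {
  need <- c("compound_id", "concentration_molar", "replicate",
            "frac_ER_retained", "frac_Golgi_disrupted")
  stopifnot(all(need %in% names(panel)))
  if (!"golgi_signal" %in% names(panel)) panel$golgi_signal <- NA_real_
  out <- list()
  n_rep_total <- length(unique(panel$replicate))
  for (id in unique(panel$compound_id)) {
    p <- panel[panel$compound_id == id, ]
    doses <- sort(unique(p$concentration_molar))
    if (length(doses) < 2) {
      warning("compound ", id, " has a single dose; excluded")
      next
    }
    prof <- do.call(rbind, lapply(doses, function(d) {
      q <- p[p$concentration_molar == d & !is.na(p$frac_ER_retained), ]
      data.frame(dose = d,
                 er_mean = mean(q$frac_ER_retained),
                 er_sd = stats::sd(q$frac_ER_retained),
                 gd_mean = mean(q$frac_Golgi_disrupted),
                 gd_sd = stats::sd(q$frac_Golgi_disrupted),
                 gs_mean = mean(q$golgi_signal),
                 n_rep = nrow(q),
                 incomplete = nrow(q) < n_rep_total)
    }))
    class(prof) <- c("dose_profile", "data.frame")
    out[[id]] <- prof
  }
  out
}

#' Detect the high-dose Golgi-disruption quantification collapse
#'
#' At high doses of the most potent trafficking inhibitors the Golgi is
#' completely disassembled: no compact structures remain, so the
#' Golgi-disrupted score falls although disruption is maximal. The flag is
#' raised when the disrupted score drops by more than `drop_frac` from its
#' maximum at some higher dose while the Golgi-signal curve at those doses is
#' below `signal_floor_frac` of its low-dose level. Genuine non-monotonicity
#' with preserved Golgi signal is not flagged.
#'
#' @param gd_curve Golgi-disrupted score per dose (ascending dose order).
#' @param gs_curve Golgi-signal readout on the same dose grid.
#' @param doses dose grid (ascending).
#' @param drop_frac fractional drop from the curve maximum that counts as a
#'   collapse.
#' @param signal_floor_frac Golgi-signal floor, as a fraction of the
#'   lowest-dose signal.
#' @param min_peak minimal curve maximum for the rule to apply.
#' @return list with `flag`, `collapse_dose` (first post-peak dose below
#'   half-max with collapsed signal; `NA` when unflagged), `peak_dose`.
#' @export
detect_high_dose_collapse <- function(gd_curve, gs_curve, doses,
                                      drop_frac = 0.5,
                                      signal_floor_frac = 0.3,
                                      min_peak = 0.1) {
  stopifnot(length(gd_curve) == length(gs_curve),
            length(gd_curve) == length(doses), !is.unsorted(doses))
  peak <- which.max(gd_curve)
  if (gd_curve[peak] < min_peak)
    return(list(flag = FALSE, collapse_dose = NA_real_, peak_dose = NA_real_))
  floor_val <- signal_floor_frac * gs_curve[1]
  post <- seq_along(doses) > peak &
    gd_curve < (1 - drop_frac) * gd_curve[peak] &
    !is.na(gs_curve) & gs_curve < floor_val
  if (!any(post))
    return(list(flag = FALSE, collapse_dose = NA_real_,
                peak_dose = doses[peak]))
  list(flag = TRUE, collapse_dose = doses[which(post)[1]],
       peak_dose = doses[peak])
}

#' Default dose-response family-rule parameters
#' @param ... named overrides.
#' @export
default_family_params <- function(...) {
  p <- list(
    min_span = 0.12,        # minimal fitted rise (response units) to count
    ic50_window_fold = 3,   # "same concentration range" window
    mt_split_criterion = "plateau",  # or "hill"
    plateau_cut = 0.75,     # disrupted-fraction plateau splitting the
                            # depolymerizer-like from the destabilizer-like
    hill_cut = 1.8,
    collapse = list(drop_frac = 0.5, signal_floor_frac = 0.3, min_peak = 0.1)
  )
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

.rise_ok <- function(fit, doses, min_span) {
  !is.null(fit) && isTRUE(fit$converged) && !isTRUE(fit$flat) &&
    (fit$top - fit$bottom) >= min_span &&
    fit$ic50 >= min(doses) / 10 && fit$ic50 <= max(doses) * 10
}

# peak dose of a bell-shaped curve, refined by log-quadratic interpolation
# around the grid maximum
.bell_peak_dose <- function(doses, curve) {
  i <- which.max(curve)
  n <- length(doses)
  if (i == 1L || i == n) return(doses[i])
  x <- log10(doses[(i - 1):(i + 1)])
  y <- curve[(i - 1):(i + 1)]
  den <- (x[2] - x[1]) * (y[2] - y[3]) - (x[2] - x[3]) * (y[2] - y[1])
  if (abs(den) < 1e-12) return(doses[i])
  xv <- x[2] - 0.5 * ((x[2] - x[1])^2 * (y[2] - y[3]) -
                        (x[2] - x[3])^2 * (y[2] - y[1])) / den
  if (xv < x[1] || xv > x[3]) return(doses[i])
  10^xv
}

# IC50 surrogate for a truncated (collapsed) rising curve: dose where the
# curve first crosses half of its maximum, by log-linear interpolation
.halfmax_dose <- function(doses, curve) {
  peak <- which.max(curve)
  half <- curve[peak] / 2
  for (i in seq_len(peak)) {
    if (curve[i] >= half) {
      if (i == 1L) return(doses[1])
      f <- (half - curve[i - 1]) / (curve[i] - curve[i - 1])
      return(10^(log10(doses[i - 1]) +
                   f * (log10(doses[i]) - log10(doses[i - 1]))))
    }
  }
  doses[peak]
}

#' Assign dose-response mechanistic families
#'
#' Rule set over the fitted ER-retained and Golgi-disrupted dose-response
#' curves of each compound (collapse correction applied before rule
#' evaluation):
#' \itemize{
#'   \item ER retention rises dose-dependently with a flat disrupted curve:
#'     `homeostasis_or_energy` (trafficking block without Golgi disassembly).
#'   \item Disrupted score rises with flat ER retention: microtubule-like,
#'     split into `mt_depolymerizer_like` (steep, near-complete disruption)
#'     vs `mt_destabilizer_like` (shallow, partial) by a configurable
#'     plateau/hill-slope shape criterion (a heuristic; the discrimination
#'     rule is not uniquely determined by the phenotype readout).
#'   \item Both rise with IC50s within a configurable fold-window (default
#'     3-fold, after collapse correction): `bfa_like`.
#'   \item Otherwise `unclassified`.
#' }
#'
#' @param profiles named list from [build_profiles()].
#' @param params rule parameters from [default_family_params()].
#' @return data.frame (`FamilyAssignment`): compound_id, family, rule,
#'   high_dose_collapse_flag, er_ic50, gd_ic50, er_hill, gd_hill, gd_plateau.
#' @export
classify_family <- function(profiles, params = default_family_params()) {
  rows <- lapply(names(profiles), function(id) {
    pr <- profiles[[id]]
    doses <- pr$dose
    er_fit <- tryCatch(fit_4pl(doses, pr$er_mean), error = function(e) NULL)
    col <- do.call(detect_high_dose_collapse,
                   c(list(gd_curve = pr$gd_mean, gs_curve = pr$gs_mean,
                          doses = doses), params$collapse))
    gd_doses <- doses
    gd_curve <- pr$gd_mean
    if (col$flag) {  # collapse correction: keep the rising portion
      keep <- doses <= col$peak_dose
      gd_doses <- doses[keep]
      gd_curve <- pr$gd_mean[keep]
    }
    gd_fit <- if (length(gd_doses) >= 4)
      tryCatch(fit_4pl(gd_doses, gd_curve), error = function(e) NULL)
    else NULL
    er_rise <- .rise_ok(er_fit, doses, params$min_span)
    gd_rise <- .rise_ok(gd_fit, doses, params$min_span)
    gd_span_obs <- max(gd_curve) - gd_curve[1]
    gd_active <- gd_rise || (col$flag && gd_span_obs >= params$min_span)
    # under collapse the disruption is transient: the (interpolated) peak
    # dose locates its activity midpoint better than a fit truncated to the
    # rising flank, whose midpoint is systematically left-shifted
    gd_ic50 <- if (col$flag && gd_active)
      .bell_peak_dose(doses, pr$gd_mean)
    else if (gd_rise) gd_fit$ic50
    else if (gd_active) .halfmax_dose(gd_doses, gd_curve)
    else NA_real_
    gd_plateau <- max(pr$gd_mean)
    family <- "unclassified"; rule <- "d"
    if (er_rise && !gd_active) {
      family <- "homeostasis_or_energy"; rule <- "a"
    } else if (gd_active && !er_rise) {
      dep <- switch(params$mt_split_criterion,
                    plateau = gd_plateau >= params$plateau_cut,
                    hill = !is.null(gd_fit) && isTRUE(gd_fit$converged) &&
                      gd_fit$hill >= params$hill_cut,
                    stop("unknown mt_split_criterion"))
      family <- if (dep) "mt_depolymerizer_like" else "mt_destabilizer_like"
      rule <- "b"
    } else if (er_rise && gd_active && !is.na(gd_ic50)) {
      ratio <- max(er_fit$ic50, gd_ic50) / min(er_fit$ic50, gd_ic50)
      if (ratio <= params$ic50_window_fold) {
        family <- "bfa_like"; rule <- "c"
      }
    }
    data.frame(compound_id = id, family = family, rule = rule,
               high_dose_collapse_flag = col$flag,
               er_ic50 = if (er_rise) er_fit$ic50 else NA_real_,
               gd_ic50 = gd_ic50,
               er_hill = if (er_rise) er_fit$hill else NA_real_,
               gd_hill = if (gd_rise) gd_fit$hill else NA_real_,
               gd_plateau = gd_plateau)
  })
  do.call(rbind, rows)
}

#' Example dose-response confirmation panel
#'
#' A 50-compound panel with known mechanistic families, mirroring the
#' confirmation-screen design: ER retainers, microtubule
#' depolymerizer-like (steep, complete disruption) and destabilizer-like
#' (shallow, partial) compounds, bfa_like compounds, and inert compounds.
#' EC50s are drawn log-uniformly within the tested dilution range.
#'
#' @param n panel size.
#' @param seed integer seed.
#' @return named list of [compound_effect()] models with attribute
#'   `true_family`.
#' @export
example_family_panel <- function(n = 50L, seed = 1L) {
  counts <- round(n * c(er_retainer = 0.24, mt_depolymerizer_like = 0.2,
                        golgi_disruptor = 0.2, bfa_like = 0.24,
                        inert = 0.12))
  counts[1] <- counts[1] + (n - sum(counts))
  classes <- rep(names(counts), counts)
  set.seed(derive_seed(seed, "family_panel"))
  ec50 <- 10^stats::runif(n, log10(5e-8), log10(6e-7))
  effects <- lapply(seq_len(n), function(i) {
    switch(classes[i],
           er_retainer = compound_effect("er_retainer", ec50[i], 1.2, 0.9),
           mt_depolymerizer_like = compound_effect("mt_depolymerizer_like",
                                                   ec50[i], 2.5, 0.95),
           golgi_disruptor = compound_effect("golgi_disruptor", ec50[i],
                                             1.0, 0.55),
           bfa_like = compound_effect("bfa_like", ec50[i], 1.2, 0.9,
                                      gd_weight = 0.6),
           inert = compound_effect("inert"))
  })
  names(effects) <- sprintf("D%03d", seq_len(n))
  true_family <- c(er_retainer = "homeostasis_or_energy",
                   mt_depolymerizer_like = "mt_depolymerizer_like",
                   golgi_disruptor = "mt_destabilizer_like",
                   bfa_like = "bfa_like", inert = "unclassified")[classes]
  attr(effects, "true_family") <- stats::setNames(unname(true_family),
                                                  names(effects))
  effects
}
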