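#' Tukey median polish with masking
#'
#' Iteratively sweeps row medians then column medians (row-first) from the
#' residuals into additive effects until the largest absolute change falls
#' below `tol` or `max_iter` is reached. Masked entries (control, empty or
#' low-count wells) are excluded from every median but still receive
#' residuals, so control wells can be scored against the fitted positional
#' model. Even-length medians are the mean of the central pair.
#'
#' `overall + row_effects[i] + col_effects[j] + residuals[i, j]` reconstructs
#' every finite input entry exactly (residuals are computed as input minus
#' fit).
#'
#' @param x numeric matrix (may contain `NA`).
#' @param use logical matrix, `TRUE` where entries enter the medians
#'   (default: all finite entries).
#' @param max_iter maximal number of full sweep cycles.
#' @param tol convergence tolerance on the largest absolute change.
#' @return list with `overall`, `row_effects`, `col_effects`, `residuals`,
#'   `converged`, `iterations`, and `flagged_rows`/`flagged_cols` (fully
#'   masked rows/columns whose effects were set to 0).
#' @export
median_polish <- function(x, use = NULL, max_iter = 20L, tol = 1e-9) {
  stopifnot(is.matrix(x))
  if (is.null(use)) use <- is.finite(x)
  stopifnot(identical(dim(use), dim(x)))
  use <- use & is.finite(x)
  z <- x
  z[!use] <- NA
  nr <- nrow(x); nc <- ncol(x)
  flagged_rows <- which(rowSums(use) == 0)
  flagged_cols <- which(colSums(use) == 0)
  overall <- 0
  row_eff <- rep(0, nr)
  col_eff <- rep(0, nc)
  med0 <- function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    delta_max <- 0
    rd <- apply(z, 1, med0)
    z <- z - rd
    row_eff <- row_eff + rd
    d <- med0(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    delta_max <- max(delta_max, abs(rd), abs(d))
    cd <- apply(z, 2, med0)
    z <- z - rep(cd, each = nr)
    col_eff <- col_eff + cd
    d <- med0(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    delta_max <- max(delta_max, abs(cd), abs(d))
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }
  row_eff[flagged_rows] <- 0
  col_eff[flagged_cols] <- 0
  fit <- overall + outer(row_eff, col_eff, "+")
  residuals <- x - fit
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = residuals, converged = converged, iterations = iter,
       flagged_rows = flagged_rows, flagged_cols = flagged_cols)
}

#' Robust Z-scores
#'
#' `RZ_i = (values_i - median(reference)) / (1.4826 * MAD(reference))`, with
#' `MAD = median(|reference - median(reference)|)`; 1.4826 makes the MAD a
#' consistent estimator of the standard deviation under normality. A zero MAD
#' yields non-finite scores, flagged via the `mad_zero` attribute.
#'
#' @param values numeric vector to score.
#' @param reference numeric reference sample (>= 3 finite entries).
#' @return numeric vector of RZ-scores with attributes `median`, `mad`,
#'   `mad_zero`.
#' @export
robust_z <- function(values, reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) == 0) stop("empty reference rejected")
  if (length(reference) < 3) stop("reference needs >= 3 finite entries")
  med <- stats::median(reference)
  madv <- stats::median(abs(reference - med))
  z <- (values - med) / (1.4826 * madv)
  structure(z, median = med, mad = madv, mad_zero = madv == 0)
}

#' Build one per-class plate matrix
#'
#' @param summaries WellSummary table.
#' @param layout plate layout.
#' @param class phenotype class.
#' @param replicate replicate id.
#' @param plate plate id.
#' @return list with `values` (rows x cols matrix of class fractions) and
#'   `use` (logical mask: sample wells with adequate cell counts).
#' @export
plate_matrix <- function(summaries, layout, class, replicate, plate) {
  format <- attr(layout, "format") %||% c(16L, 24L)
  sel_l <- layout$plate == plate & layout$replicate == replicate
  lay <- layout[sel_l, ]
  sel_s <- summaries$plate == plate & summaries$replicate == replicate
  sm <- summaries[sel_s, ]
  values <- matrix(NA_real_, format[1], format[2])
  use <- matrix(FALSE, format[1], format[2])
  m <- match(lay$well, sm$well)
  v <- sm[[paste0("frac_", class)]][m]
  low <- sm$low_count[m]
  idx <- cbind(lay$row, lay$col)
  values[idx] <- v
  use[idx] <- lay$control_role == "sample" & !is.na(v) &
    !(low %in% TRUE)
  list(values = values, use = use)
}

#' Score plates: median polish then robust Z per class and replicate
#'
#' For each phenotype class and replicate: build the plate matrix, remove
#' positional effects by [median_polish()] (optional), then compute robust
#' Z-scores of the residuals against the reference population of sample-well
#' residuals of that replicate — the screening data points themselves, under
#' the assumption that most compounds are inactive. Control wells are scored
#' against the same reference but never contribute to it.
#'
#' @param summaries WellSummary table covering all sample wells.
#' @param layout plate layout.
#' @param classes phenotype classes to score.
#' @param polish apply median polish before scoring (a switch to skip it is
#'   provided; the polish-then-RZ order is the standard B-score-style
#'   pipeline).
#' @param max_iter,tol polish controls.
#' @return long data.frame (`RZScoreTable`): plate, replicate, well, row,
#'   col, compound_id, control_role, class, value, residual, rz, ref_median,
#'   ref_mad, mad_zero, low_count.
#' @export
score_plates <- function(summaries, layout, classes = PHENOTYPE_CLASSES,
                         polish = TRUE, max_iter = 20L, tol = 1e-9) {
  plates <- unique(layout$plate)
  reps <- unique(layout$replicate)
  out <- list()
  for (pl in plates) {
    for (rp in reps) {
      lay <- layout[layout$plate == pl & layout$replicate == rp, ]
      if (!nrow(lay)) next
      for (cl in classes) {
        pm <- plate_matrix(summaries, layout, cl, rp, pl)
        if (!any(pm$use))
          stop("replicate ", rp, " of plate ", pl,
               " has no usable sample wells for class ", cl)
        resid <- if (polish) {
          median_polish(pm$values, pm$use, max_iter, tol)$residuals
        } else {
          pm$values
        }
        reference <- resid[pm$use]
        rz <- robust_z(resid[cbind(lay$row, lay$col)], reference)
        sm <- summaries[summaries$plate == pl & summaries$replicate == rp, ]
        m <- match(lay$well, sm$well)
        out[[length(out) + 1L]] <- data.frame(
          plate = pl, replicate = rp, well = lay$well,
          row = lay$row, col = lay$col,
          compound_id = lay$compound_id, control_role = lay$control_role,
          class = cl,
          value = pm$values[cbind(lay$row, lay$col)],
          residual = resid[cbind(lay$row, lay$col)],
          rz = as.numeric(rz),
          ref_median = attr(rz, "median"), ref_mad = attr(rz, "mad"),
          mad_zero = attr(rz, "mad_zero"),
          low_count = sm$low_count[m] %in% TRUE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Call hits from an RZ-score table
#'
#' A replicate is hit-positive for a compound and class when `RZ < -threshold`
#' or `RZ > threshold` (strictly; an RZ of exactly 2 is not a hit). Replicate
#' calls are aggregated per compound (`majority` by default). Low-count
#' (toxic) wells are excluded. Each hit is annotated with its triggering
#' class(es) and sign; the hit list is sorted by the ER-retained score.
#'
#' @param scores RZ table from [score_plates()].
#' @param threshold positive hit threshold (default 2).
#' @param aggregation one of `"majority"`, `"all"`, `"any"`.
#' @param classes classes to evaluate.
#' @return data.frame per (compound, class): per-replicate RZ (`rz_rep<k>`),
#'   `n_hit_reps`, `n_reps`, `hit`, `sign`, `mean_rz`; attribute `hit_list`
#'   (compound-level hit table with triggering classes, sorted by the
#'   ER-retained score).
#' @export
call_hits <- function(scores, threshold = 2, aggregation = c("majority",
                                                             "all", "any"),
                      classes = PHENOTYPE_CLASSES) {
  if (threshold <= 0) stop("threshold must be positive")
  aggregation <- match.arg(aggregation)
  s <- scores[scores$control_role == "sample" & !scores$low_count &
                scores$class %in% classes, ]
  reps <- sort(unique(s$replicate))
  rows <- list()
  for (cmp in unique(s$compound_id)) {
    for (cl in classes) {
      sel <- s[s$compound_id == cmp & s$class == cl, ]
      if (!nrow(sel)) next
      rz <- vapply(reps, function(r) {
        v <- sel$rz[sel$replicate == r]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      hit_rep <- !is.na(rz) & is.finite(rz) & (rz < -threshold | rz > threshold)
      n_reps <- sum(!is.na(rz))
      n_hit <- sum(hit_rep)
      hit <- switch(aggregation,
                    majority = n_hit >= ceiling((n_reps + 1) / 2),
                    all = n_reps > 0 && n_hit == n_reps,
                    any = n_hit > 0)
      row <- data.frame(compound_id = cmp, class = cl,
                        mean_rz = mean(rz, na.rm = TRUE),
                        n_hit_reps = n_hit, n_reps = n_reps, hit = hit,
                        sign = sign(mean(rz[hit_rep])))
      for (k in seq_along(reps)) row[[paste0("rz_rep", reps[k])]] <- rz[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$sign[!out$hit] <- NA_real_
  # compound-level hit list, triggering classes, sorted by ER-retained score
  hits <- out[out$hit, , drop = FALSE]
  if (nrow(hits)) {
    by_cmp <- split(hits, hits$compound_id)
    hl <- do.call(rbind, lapply(by_cmp, function(h) {
      er <- out$mean_rz[out$compound_id == h$compound_id[1] &
                          out$class == "ER_retained"]
      data.frame(compound_id = h$compound_id[1],
                 classes = paste(h$class, collapse = ";"),
                 signs = paste(h$sign, collapse = ";"),
                 er_retained_rz = if (length(er)) er else NA_real_)
    }))
    hl <- hl[order(-hl$er_retained_rz), ]
    rownames(hl) <- NULL
  } else {
    hl <- data.frame(compound_id = character(0), classes = character(0),
                     signs = character(0), er_retained_rz = numeric(0))
  }
  attr(out, "hit_list") <- hl
  out
}
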