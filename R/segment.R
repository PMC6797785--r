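#' Default segmentation parameters
#'
#' Operator parameters for the per-cell image analysis. The exact parameters
#' of the original instrument software are unpublished; these defaults were
#' tuned on the synthetic generator and are all config-exposed.
#'
#' @param ... named overrides.
#' @return list of class `seg_params`.
#' @export
default_seg_params <- function(...) {
  p <- list(
    tophat_radius_px = 8L,          # about one nucleus radius above the mean
    threshold_method = "otsu",
    min_nucleus_area_px = 20L,
    split_touching = TRUE,
    collar_radius_px = 6L,
    exclude_nucleus_from_collar = FALSE,
    inclusion_scales_px = c(2L, 3L),
    inclusion_threshold_method = "mad", # median + k * 1.4826 * MAD of response
    inclusion_mad_k = 6,
    inclusion_min_response = 0.12,      # absolute response floor
    inclusion_halfmax_refine = TRUE,
    inclusion_smooth_sigma = 0.6,   # denoising blur for delineation only
    inclusion_split_by_region = FALSE,  # TRUE: cut components at region
                                        # boundaries instead of assigning the
                                        # whole object to the peak's cell
    min_inclusion_area_px = 2L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown segmentation parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "seg_params")
}

.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(lab, u, nomatch = 0L) , nrow(lab), ncol(lab))
  out[is.na(out)] <- 0L
  out
}

#' Segment nuclei from the DNA channel
#'
#' White top-hat with a disk structuring element, global threshold (Otsu by
#' default), area filter, and optional watershed splitting of touching
#' components.
#'
#' @param dna_channel numeric matrix (DNA staining), values >= 0.
#' @param params segmentation parameters ([default_seg_params()]).
#' @return integer label matrix (background 0, labels 1..n).
#' @export
segment_nuclei <- function(dna_channel, params = default_seg_params()) {
  stopifnot(is.matrix(dna_channel), length(dna_channel) > 0)
  r <- params$tophat_radius_px
  th <- EBImage::whiteTopHat(dna_channel, EBImage::makeBrush(2L * r + 1L, "disc"))
  mx <- max(th)
  if (mx <= 0) return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  thr <- switch(params$threshold_method,
                otsu = EBImage::otsu(th / mx, range = c(0, 1)) * mx,
                stop("unknown threshold_method: ", params$threshold_method))
  bin <- th > thr
  if (!any(bin)) return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  lab <- if (isTRUE(params$split_touching)) {
    dm <- EBImage::distmap(bin)
    EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(bin))
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  area <- tabulate(lab[lab > 0])
  drop <- which(area < params$min_nucleus_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  .relabel(lab)
}

#' Collar cell regions around nuclei
#'
#' Each cell region is its nucleus dilated by `collar_radius_px`, with
#' contested pixels assigned to the nearest nucleus (exact Euclidean
#' distance-transform partition; ties broken by the lower label). Regions are
#' pairwise disjoint, each contains its nucleus, and their union equals the
#' dilated-nuclei support.
#'
#' @param nucleus_mask integer label matrix from [segment_nuclei()].
#' @param collar_radius_px non-negative dilation radius in pixels.
#' @return integer label matrix of cell regions (same labels as nuclei).
#' @export
collar_cell_regions <- function(nucleus_mask, collar_radius_px) {
  stopifnot(is.matrix(nucleus_mask))
  if (collar_radius_px < 0) stop("collar_radius_px must be >= 0")
  labels <- sort(unique(nucleus_mask[nucleus_mask > 0]))
  if (!length(labels) || collar_radius_px == 0)
    return(matrix(as.integer(nucleus_mask), nrow(nucleus_mask), ncol(nucleus_mask)))
  brush <- EBImage::makeBrush(2L * as.integer(collar_radius_px) + 1L, "disc")
  support <- EBImage::imageData(EBImage::dilate(nucleus_mask > 0, brush)) > 0
  best_d <- matrix(Inf, nrow(nucleus_mask), ncol(nucleus_mask))
  best_l <- matrix(0L, nrow(nucleus_mask), ncol(nucleus_mask))
  for (l in labels) {
    d <- EBImage::imageData(EBImage::distmap(1 - (nucleus_mask == l)))
    upd <- support & (d < best_d)
    best_d[upd] <- d[upd]
    best_l[upd] <- l
  }
  best_l
}

#' Detect cargo inclusions by multiscale top-hat
#'
#' Pixel-wise maximum of white top-hats over the given disk scales,
#' thresholded within the cell regions; inclusion pixels are restricted to the
#' collar regions. Candidate components are optionally refined to pixels above
#' half of the component's peak response (FWHM-style delineation), and
#' components are split along cell-region boundaries.
#'
#' @param egfp_channel numeric matrix (cargo channel).
#' @param cell_regions label matrix from [collar_cell_regions()].
#' @param params segmentation parameters; `inclusion_scales_px` must be a
#'   non-empty ascending list of disk radii.
#' @return list with `labels` (integer matrix of inclusion components),
#'   `cell_of` (integer vector mapping component -> cell label), and
#'   `response` (the multiscale top-hat response).
#' @export
detect_inclusions <- function(egfp_channel, cell_regions,
                              params = default_seg_params()) {
  scales <- params$inclusion_scales_px
  if (length(scales) == 0) stop("empty inclusion scale list rejected")
  if (is.unsorted(scales)) stop("inclusion scales must be ascending")
  resp <- matrix(0, nrow(egfp_channel), ncol(egfp_channel))
  for (s in scales) {
    th <- EBImage::whiteTopHat(egfp_channel,
                               EBImage::makeBrush(2L * s + 1L, "disc"))
    resp <- pmax(resp, th)
  }
  inside <- cell_regions > 0
  empty <- list(labels = matrix(0L, nrow(resp), ncol(resp)),
                cell_of = integer(0), response = resp)
  if (!any(inside)) return(empty)
  vals <- resp[inside]
  thr <- switch(params$inclusion_threshold_method,
    mad = stats::median(vals) +
      params$inclusion_mad_k * 1.4826 * stats::mad(vals, constant = 1),
    otsu = {
      mx <- max(vals)
      if (mx <= 0) Inf else EBImage::otsu(resp / mx, range = c(0, 1)) * mx
    },
    stop("unknown inclusion_threshold_method: ",
         params$inclusion_threshold_method))
  thr <- max(thr, params$inclusion_min_response)
  bin <- (resp > thr) & inside
  if (!any(bin)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  idx <- which(lab > 0)
  comp <- matrix(0L, nrow(lab), ncol(lab))
  if (isTRUE(params$inclusion_split_by_region)) {
    # strict pixel-level restriction: cut components at region boundaries
    pair <- paste(lab[idx], cell_regions[idx])
    comp[idx] <- match(pair, unique(pair))
  } else {
    # object-level assignment: a compact structure straddling the boundary
    # between two cell regions stays whole and belongs to the cell whose
    # region holds its peak response (avoids biasing the mean-intensity
    # readout for juxtanuclear inclusions near region midlines)
    comp[idx] <- as.integer(lab[idx])
    comp <- .relabel(comp)
    idx <- which(comp > 0)
  }
  if (isTRUE(params$inclusion_halfmax_refine)) {
    # delineate each component at half-maximum of the raw signal above the
    # local (collar) background, so the measured region tracks the physical
    # extent of the structure rather than the top-hat response support
    img_s <- if (params$inclusion_smooth_sigma > 0)
      EBImage::gblur(egfp_channel, sigma = params$inclusion_smooth_sigma)
    else egfp_channel
    cell_bg <- vapply(split(img_s[inside & !bin],
                            cell_regions[inside & !bin]),
                      stats::median, numeric(1))
    comp_cell <- as.character(.comp_cells(comp, idx, resp, cell_regions))
    names(comp_cell) <- seq_along(comp_cell)
    peaks <- vapply(split(img_s[idx], comp[idx]), max, numeric(1))
    bg <- cell_bg[comp_cell[as.character(comp[idx])]]
    bg[is.na(bg)] <- 0
    half <- bg + 0.5 * (peaks[as.character(comp[idx])] - bg)
    keep <- img_s[idx] >= half
    comp[idx[!keep]] <- 0L
    comp <- .relabel(comp)
    idx <- which(comp > 0)
  }
  if (params$min_inclusion_area_px > 1 && length(idx)) {
    area <- tabulate(comp[idx])
    small <- which(area < params$min_inclusion_area_px)
    if (length(small)) {
      comp[comp %in% small] <- 0L
      comp <- .relabel(comp)
      idx <- which(comp > 0)
    }
  }
  cell_of <- .comp_cells(comp, idx, resp, cell_regions)
  list(labels = comp, cell_of = cell_of, response = resp)
}

# component -> owning cell: the region holding the component's peak response
.comp_cells <- function(comp, idx, resp, cell_regions) {
  if (!length(idx)) return(integer(0))
  vapply(split(idx, comp[idx]), function(ii)
    as.integer(cell_regions[ii[which.max(resp[ii])]]), integer(1),
    USE.NAMES = FALSE)
}

#' Extract per-cell features
#'
#' One record per nucleus: nucleus geometry, collar region area, inclusion
#' area/count and intensity statistics (mean intensity measured on the raw
#' cargo channel, not the top-hat transform), collar mean intensity, the
#' inclusion-to-collar intensity ratio (undefined, `NA`, when the cell has no
#' inclusion), and a border-touching flag.
#'
#' @param field a field object with `channels$egfp` (list as produced by
#'   [render_field()]/[read_field_images()]).
#' @param nuclei nucleus label matrix.
#' @param regions cell-region label matrix (same label set).
#' @param inclusions result of [detect_inclusions()].
#' @return data.frame with one row per cell.
#' @export
extract_cell_features <- function(field, nuclei, regions, inclusions) {
  egfp <- field$channels$egfp
  lab_n <- sort(unique(nuclei[nuclei > 0]))
  lab_r <- sort(unique(regions[regions > 0]))
  if (!identical(lab_n, lab_r))
    stop("label mismatch between nucleus and region masks")
  if (!length(lab_n)) {
    return(data.frame(cell = integer(0), nucleus_area = numeric(0),
                      x = numeric(0), y = numeric(0),
                      collar_area = numeric(0), collar_mean = numeric(0),
                      inclusion_area = numeric(0), inclusion_count = integer(0),
                      inclusion_mean = numeric(0), inclusion_total = numeric(0),
                      inclusion_collar_ratio = numeric(0),
                      border = logical(0)))
  }
  nr <- nrow(egfp); nc <- ncol(egfp)
  n_idx <- which(nuclei > 0)
  n_lab <- nuclei[n_idx]
  rowp <- (n_idx - 1L) %% nr + 1L
  colp <- (n_idx - 1L) %/% nr + 1L
  nucleus_area <- tabulate(n_lab, max(lab_n))
  cy <- vapply(split(rowp, n_lab), mean, numeric(1)) - 1  # 0-based, row-major
  cx <- vapply(split(colp, n_lab), mean, numeric(1)) - 1

  r_idx <- which(regions > 0)
  r_lab <- regions[r_idx]
  collar_area <- tabulate(r_lab, max(lab_n))
  collar_sum <- vapply(split(egfp[r_idx], r_lab), sum, numeric(1))
  rrow <- (r_idx - 1L) %% nr + 1L
  rcol <- (r_idx - 1L) %/% nr + 1L
  on_border <- rrow == 1L | rrow == nr | rcol == 1L | rcol == nc
  border <- vapply(split(on_border, r_lab), any, logical(1))

  inc_area <- inc_count <- inc_total <- rep(0, max(lab_n))
  i_idx <- which(inclusions$labels > 0)
  if (length(i_idx)) {
    comp <- inclusions$labels[i_idx]
    comp_area <- tabulate(comp)
    comp_sum <- vapply(split(egfp[i_idx], comp), sum, numeric(1))
    for (k in seq_along(inclusions$cell_of)) {
      cl <- inclusions$cell_of[k]
      inc_area[cl] <- inc_area[cl] + comp_area[k]
      inc_count[cl] <- inc_count[cl] + 1
      inc_total[cl] <- inc_total[cl] + comp_sum[k]
    }
  }
  lab_chr <- as.character(lab_n)
  out <- data.frame(
    cell = lab_n,
    nucleus_area = nucleus_area[lab_n],
    x = unname(cx[lab_chr]), y = unname(cy[lab_chr]),
    collar_area = collar_area[lab_n],
    collar_mean = unname(collar_sum[lab_chr]) / collar_area[lab_n],
    inclusion_area = inc_area[lab_n],
    inclusion_count = as.integer(inc_count[lab_n]),
    inclusion_mean = ifelse(inc_area[lab_n] > 0,
                            inc_total[lab_n] / inc_area[lab_n], NA_real_),
    inclusion_total = inc_total[lab_n],
    border = unname(border[lab_chr])
  )
  out$inclusion_collar_ratio <- ifelse(out$inclusion_area > 0,
                                       out$inclusion_mean / out$collar_mean,
                                       NA_real_)
  stopifnot(all(out$inclusion_area <= out$collar_area))
  out
}

#' Segment one field end to end
#'
#' Nuclei -> collar regions -> inclusions -> per-cell feature records, with
#' field provenance attached.
#'
#' @param field field object (`channels` plus `plate`/`well`/`field`/
#'   `replicate` when present).
#' @param params segmentation parameters.
#' @return per-cell feature data.frame.
#' @export
segment_field <- function(field, params = default_seg_params()) {
  nuclei <- segment_nuclei(field$channels$dna, params)
  regions <- collar_cell_regions(nuclei, params$collar_radius_px)
  incl <- detect_inclusions(field$channels$egfp, regions, params)
  feats <- extract_cell_features(field, nuclei, regions, incl)
  if (nrow(feats)) {
    feats$plate <- field$plate %||% NA_character_
    feats$well <- field$well %||% NA_character_
    feats$field <- field$field %||% NA_integer_
    feats$replicate <- field$replicate %||% NA_integer_
  }
  feats
}

#' Segment a set of fields into one cell table
#'
#' @param fields list of field objects.
#' @param params segmentation parameters.
#' @return combined per-cell feature data.frame (CellRecord table).
#' @export
segment_fields <- function(fields, params = default_seg_params()) {
  tabs <- lapply(fields, segment_field, params = params)
  do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
}

#' Match segmented cells to simulation ground truth
#'
#' Greedy nearest-centroid matching within each (plate, well, replicate,
#' field) group, up to `max_dist` pixels.
#'
#' @param features segmented cell table ([segment_fields()]).
#' @param truth_cells ground-truth cell table from a rendered simulation.
#' @param max_dist maximal centroid distance (px).
#' @return `features` with ground-truth columns (`phenotype`,
#'   `true_inclusion_mean`, ...) appended; unmatched cells carry `NA`.
#' @export
match_cells_to_truth <- function(features, truth_cells, max_dist = 6) {
  features$true_phenotype <- NA_character_
  features$true_inclusion_mean <- NA_real_
  features$true_inclusion_area <- NA_real_
  features$true_n_puncta <- NA_integer_
  fkey <- paste(features$plate, features$well, features$replicate,
                features$field)
  tkey <- paste(truth_cells$plate, truth_cells$well, truth_cells$replicate,
                truth_cells$field)
  for (k in unique(fkey)) {
    fi <- which(fkey == k)
    ti <- which(tkey == k)
    if (!length(ti)) next
    d <- outer(features$x[fi], truth_cells$x[ti], "-")^2 +
         outer(features$y[fi], truth_cells$y[ti], "-")^2
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > max_dist^2) break
      i <- (m - 1L) %% length(fi) + 1L
      j <- (m - 1L) %/% length(fi) + 1L
      features$true_phenotype[fi[i]] <- truth_cells$phenotype[ti[j]]
      features$true_inclusion_mean[fi[i]] <- truth_cells$true_inclusion_mean[ti[j]]
      features$true_inclusion_area[fi[i]] <- truth_cells$true_inclusion_area[ti[j]]
      features$true_n_puncta[fi[i]] <- truth_cells$n_puncta[ti[j]]
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  features
}
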