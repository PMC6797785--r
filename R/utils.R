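#' Phenotype class labels, in fixed order
#'
#' The four cargo-localization classes used throughout the pipeline. The order
#' is fixed and is also the tie-breaking order of the classifier.
#' @export
PHENOTYPE_CLASSES <- c("ER_retained", "ER_plus_Golgi", "Golgi", "Golgi_disrupted")

#' Control-role vocabulary for plate maps
#' @export
CONTROL_ROLES <- c("DMSO", "DMSO_biotin", "BFA", "BFA_biotin",
                   "NOCO", "NOCO_biotin", "sample")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible RNG sub-stream seed
#'
#' Hashes a key (e.g. plate/well/stage identifiers) together with a master seed
#' into a 32-bit integer, so that wells and stages get independent,
#' order-insensitive RNG streams.
#'
#' @param seed master integer seed.
#' @param ... key components (coerced to character, joined with "/").
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Convert well addresses to row/column indices and back
#'
#' Wells are addressed as letter-row + zero-padded column, e.g. `"B03"`.
#'
#' @param well character vector of well addresses.
#' @param format integer vector `c(rows, cols)` of the plate format
#'   (default 16 x 24 = 384-well).
#' @return `well_to_rc`: a data.frame with `row` and `col` indices (1-based);
#'   `rc_to_well`: a character vector of addresses.
#' @export
well_to_rc <- function(well, format = c(16L, 24L)) {
  stopifnot(is.character(well))
  m <- regmatches(well, regexec("^([A-Z])([0-9]{2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(well[bad], collapse = ", "))
  }
  row <- match(vapply(m, `[`, character(1), 2L), LETTERS)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  oob <- row > format[1] | col < 1L | col > format[2]
  if (any(oob)) {
    stop("well address out of plate bounds (", format[1], "x", format[2],
         "): ", paste(well[oob], collapse = ", "))
  }
  data.frame(row = row, col = col)
}

#' @rdname well_to_rc
#' @param row,col integer indices (1-based).
#' @export
rc_to_well <- function(row, col, format = c(16L, 24L)) {
  stopifnot(all(row >= 1L & row <= format[1]), all(col >= 1L & col <= format[2]))
  paste0(LETTERS[row], sprintf("%02d", col))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Serial dilution series
#'
#' @param start top concentration (molar).
#' @param n number of doses.
#' @param fold dilution factor between consecutive doses.
#' @return concentrations in ascending order.
#' @export
dilution_series <- function(start = 1e-5, n = 8, fold = 3) {
  stopifnot(start > 0, n >= 1, fold > 1)
  sort(start / fold^(seq_len(n) - 1))
}
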