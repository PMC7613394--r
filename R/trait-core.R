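# Trait formulas shared by every retrieval strategy.
#
# Traits: LAI (leaf area index, m2/m2), LCC (leaf chlorophyll content,
# ug/cm2), Cv (vertical crown cover, fraction). fCover and CCC are derived:
#   fCover = Cv * (1 - exp(-K * LAI))   (Beer-Lambert gap fraction, K = 0.55)
#   CCC    = 0.01 * LAI * LCC           (canopy chlorophyll, g/m2)

#' Convert a SPAD meter reading to leaf chlorophyll content
#'
#' Exponential transfer function for a SPAD-502 chlorophyll meter,
#' `LCC = 0.0913 * exp(0.0415 * SPAD)`. The function is applied exactly as
#' published; note its output scale sits far below typical ug/cm2 leaf
#' chlorophyll values, so treat results as the instrument-calibration scale
#' rather than absolute chlorophyll (see the methods vignette).
#'
#' @param spad Numeric vector of non-negative SPAD readings (unitless).
#' @return Numeric vector of leaf chlorophyll values.
#' @examples
#' spad_to_lcc(c(0, 50))
#' @export
spad_to_lcc <- function(spad) {
  check_numeric(spad, "spad", lower = 0)
  0.0913 * exp(0.0415 * spad)
}

# Inverse of spad_to_lcc; used to emit SPAD metadata for synthetic plots.
lcc_to_spad <- function(lcc) {
  check_numeric(lcc, "lcc", lower = 1e-12)
  log(lcc / 0.0913) / 0.0415
}

#' Fractional vegetation cover from crown cover and leaf area index
#'
#' Beer-Lambert gap-fraction model: `fCover = Cv * (1 - exp(-k * LAI))`,
#' with extinction coefficient `k = 0.55` by default.
#'
#' @param cv Vertical crown cover, fraction in \[0, 1\].
#' @param lai Leaf area index, m2/m2, non-negative.
#' @param k Extinction coefficient (> 0), default 0.55.
#' @return fCover in \[0, cv\]; vectorized over `cv` and `lai`.
#' @examples
#' fcover_from(cv = 0.71, lai = 2.85)
#' @export
fcover_from <- function(cv, lai, k = 0.55) {
  check_numeric(cv, "cv", lower = 0, upper = 1)
  check_numeric(lai, "lai", lower = 0)
  check_scalar(k, "k", lower = 1e-12)
  cv * (1 - exp(-k * lai))
}

#' Canopy chlorophyll content from LAI and leaf chlorophyll
#'
#' `CCC = 0.01 * LAI * LCC`: leaf-level chlorophyll (ug/cm2) scaled to the
#' canopy (g/m2); 1 ug/cm2 equals 0.01 g/m2.
#'
#' @param lai Leaf area index, m2/m2, non-negative.
#' @param lcc Leaf chlorophyll content, ug/cm2, non-negative.
#' @return Canopy chlorophyll content, g/m2.
#' @examples
#' ccc_from(lai = 2.85, lcc = 65.36)
#' @export
ccc_from <- function(lai, lcc) {
  check_numeric(lai, "lai", lower = 0)
  check_numeric(lcc, "lcc", lower = 0)
  0.01 * lai * lcc
}

#' Complete a trait table with derived fCover and CCC
#'
#' @param traits Data frame with columns `lai`, `lcc`, `cv` (and optionally
#'   others, carried through).
#' @param k Extinction coefficient passed to [fcover_from()].
#' @return Tibble with `fcover` and `ccc` columns (re)computed.
#' @export
derive_traits <- function(traits, k = 0.55) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("lai", "lcc", "cv") %in% names(traits)))
  dplyr::mutate(traits,
    fcover = fcover_from(.data$cv, .data$lai, k = k),
    ccc = ccc_from(.data$lai, .data$lcc)
  )
}
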