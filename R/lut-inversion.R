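# LUT-based inversion: RMSE cost against every LUT spectrum, median (or
# mean) of the q best-matching entries as the retrieved trait combination.

#' Spectral root-mean-square difference
#'
#' `sqrt(mean((a - b)^2))` over bands; the inversion cost function.
#'
#' @param a,b Numeric reflectance vectors of equal length.
#' @return Non-negative scalar; 0 iff the spectra are identical.
#' @export
spectral_rmse <- function(a, b) {
  if (length(a) != length(b)) abort("spectra must have equal band counts")
  check_numeric(a, "a")
  check_numeric(b, "b")
  sqrt(mean((a - b)^2))
}

# Cost matrix trick: RMSE^2 between each row of X (m x p) and each row of
# LUT spectra S (n x p) via the expansion |x|^2 + |s|^2 - 2 x.s, all BLAS.
rmse_cost_matrix <- function(X, S) {
  p <- ncol(S)
  cross <- X %*% t(S)
  sq <- outer(rowSums(X^2), rowSums(S^2), `+`) - 2 * cross
  sqrt(pmax(sq, 0) / p)
}

#' Invert measured spectra against a LUT
#'
#' For each input spectrum the RMSE cost to every LUT spectrum is computed,
#' entries are sorted ascending (stable: cost ties keep LUT row order), and
#' the per-variable median (or mean) of the `q` best entries is returned.
#' Derived fCover and CCC are aggregated from the per-entry derived values
#' (`derived = "aggregate"`) or recomputed from the aggregated free
#' variables (`derived = "recompute"`).
#'
#' @param spectra Wide tibble with `b<center>` columns, or a reflectance
#'   matrix whose columns match the LUT bands.
#' @param lut [build_lut()] result.
#' @param q Number of best entries to aggregate (default 300).
#' @param stat `"median"` or `"mean"`.
#' @param derived How to obtain fCover/CCC, see Details.
#' @param method Method label stamped on the output rows.
#' @return Tibble of class `trait_estimates`: one row per input spectrum
#'   with columns `lai`, `lcc`, `cv`, `fcover`, `ccc`, `cost` (best-entry
#'   RMSE), `method`, `q`.
#' @examples
#' lut <- build_lut(n = 200, noise_sigma = 0, seed = 1)
#' est <- lut_invert(lut$spectra[1:3, ], lut, q = 1)
#' est$lai
#' @export
lut_invert <- function(spectra, lut, q = 300, stat = c("median", "mean"),
                       derived = c("aggregate", "recompute"),
                       method = paste0("LUT", lut$mode)) {
  stat <- match.arg(stat)
  derived <- match.arg(derived)
  stopifnot(inherits(lut, "trait_lut"))
  X <- if (is.data.frame(spectra)) spectral_matrix(spectra) else
    if (is.null(dim(spectra))) matrix(spectra, nrow = 1) else
      as.matrix(spectra)
  n <- nrow(lut$spectra)
  if (n == 0) abort("empty LUT")
  check_scalar(q, "q", lower = 1)
  if (q > n) abort(sprintf("q = %d exceeds the LUT size %d", q, n))
  if (ncol(X) != ncol(lut$spectra)) {
    abort("spectra band count does not match the LUT")
  }
  agg <- if (stat == "median") median else mean
  vars <- intersect(c("lai", "lcc", "cv", "fcover", "ccc"),
                    names(lut$traits))
  traits <- as.matrix(lut$traits[vars])
  cost <- rmse_cost_matrix(X, lut$spectra)
  rows <- lapply(seq_len(nrow(X)), function(i) {
    best <- sort.int(cost[i, ], index.return = TRUE, method = "radix")
    idx <- best$ix[seq_len(q)]
    est <- apply(traits[idx, , drop = FALSE], 2, agg)
    if (derived == "recompute") {
      est["fcover"] <- fcover_from(est[["cv"]], est[["lai"]])
      est["ccc"] <- ccc_from(est[["lai"]], est[["lcc"]])
    }
    c(est, cost = best$x[1])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$method <- method
  out$q <- as.integer(q)
  class(out) <- c("trait_estimates", class(out))
  out
}

#' @rdname lut_invert
#' @param ... Passed on to [lut_invert()].
#' @export
lut_invert_batch <- function(spectra, lut, ...) {
  lut_invert(spectra, lut, ...)
}
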