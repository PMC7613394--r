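# Sensor band model, Gaussian spectral resampling, and noise injection.

#' Band model of a two-camera VNIR snapshot sensor
#'
#' Builds the 40-band layout of a dual snapshot system: 25 visible bands with
#' centers evenly spaced on \[474, 638\] nm (FWHM rising linearly 16 to 27
#' nm) and 16 near-infrared bands evenly spaced on \[638, 915\] nm (FWHM 15
#' to 27 nm). The two cameras overlap at 638 nm, so that center appears
#' twice; the last concatenated NIR band (the 41st) is dropped because of a
#' known unexplained reflectance artifact, leaving 40 bands.
#'
#' @param vis_range,nir_range Numeric length-2 center ranges (nm).
#' @param n_vis,n_nir Band counts per camera before dropping the 41st.
#' @param vis_fwhm,nir_fwhm Length-2 FWHM ranges (nm), linearly interpolated
#'   across each camera's bands.
#' @param drop_last Drop the final concatenated band (default `TRUE`).
#' @return Tibble of class `sensor_model` with columns `band`, `center`,
#'   `fwhm`, `region`.
#' @examples
#' nrow(gamaya_sensor())
#' @export
gamaya_sensor <- function(vis_range = c(474, 638), nir_range = c(638, 915),
                          n_vis = 25, n_nir = 16,
                          vis_fwhm = c(16, 27), nir_fwhm = c(15, 27),
                          drop_last = TRUE) {
  sensor <- tibble::tibble(
    center = c(
      seq(vis_range[1], vis_range[2], length.out = n_vis),
      seq(nir_range[1], nir_range[2], length.out = n_nir)
    ),
    fwhm = c(
      seq(vis_fwhm[1], vis_fwhm[2], length.out = n_vis),
      seq(nir_fwhm[1], nir_fwhm[2], length.out = n_nir)
    ),
    region = rep(c("vis", "nir"), c(n_vis, n_nir))
  )
  if (drop_last) sensor <- sensor[-nrow(sensor), ]
  sensor <- tibble::add_column(sensor, band = seq_len(nrow(sensor)),
                               .before = 1)
  if (is.unsorted(sensor$center)) {
    abort("band centers must be non-decreasing")
  }
  class(sensor) <- c("sensor_model", class(sensor))
  sensor
}

#' Resample fine-grid spectra to a sensor's bands
#'
#' Convolves each spectrum with a Gaussian spectral response per band,
#' centered at the band center with the band's FWHM, normalized to unit area
#' on the input grid (so a spectrally flat input is reproduced exactly).
#'
#' @param spectra Matrix (rows = observations, columns = wavelengths) or a
#'   numeric vector for a single spectrum.
#' @param grid Wavelength grid of the input columns (nm), fine (~1 nm) and
#'   covering `center +/- 2 * fwhm` for every band.
#' @param sensor [gamaya_sensor()]-style tibble.
#' @return Matrix of band reflectances, rows matching the input.
#' @export
resample_to_sensor <- function(spectra, grid, sensor = gamaya_sensor()) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  stopifnot(ncol(spectra) == length(grid))
  lo <- sensor$center - 2 * sensor$fwhm
  hi <- sensor$center + 2 * sensor$fwhm
  bad <- which(lo < min(grid) | hi > max(grid))
  if (length(bad)) {
    abort(sprintf(
      "input grid [%g, %g] nm does not cover band %d (needs [%g, %g] nm)",
      min(grid), max(grid), bad[1], lo[bad[1]], hi[bad[1]]
    ))
  }
  sigma <- sensor$fwhm / (2 * sqrt(2 * log(2)))
  w <- vapply(seq_len(nrow(sensor)), function(b) {
    resp <- dnorm(grid, mean = sensor$center[b], sd = sigma[b])
    resp / sum(resp)
  }, numeric(length(grid)))
  out <- spectra %*% w
  dimnames(out) <- NULL
  out
}

#' Inject Gaussian noise into reflectance spectra
#'
#' Adds per-band Gaussian noise to simulated spectra (default sigma 0.005
#' reflectance units, i.e. 0.5%). `mode = "additive"` perturbs
#' `r + eps`; `mode = "multiplicative"` uses `r * (1 + eps)`. Results are
#' clipped to \[0, 1\].
#'
#' @param spectra Matrix or vector of reflectances in \[0, 1\].
#' @param sigma Noise standard deviation (>= 0).
#' @param mode `"additive"` or `"multiplicative"`.
#' @param seed Optional integer seed for reproducibility.
#' @return Matrix of the same shape.
#' @export
add_noise <- function(spectra, sigma = 0.005,
                      mode = c("additive", "multiplicative"), seed = NULL) {
  mode <- match.arg(mode)
  check_scalar(sigma, "sigma", lower = 0)
  vec <- is.null(dim(spectra))
  if (vec) spectra <- matrix(spectra, nrow = 1)
  if (sigma == 0) {
    return(spectra)
  }
  out <- with_seed(seed, {
    eps <- matrix(rnorm(length(spectra), sd = sigma),
                  nrow(spectra), ncol(spectra))
    if (mode == "additive") spectra + eps else spectra * (1 + eps)
  })
  pmin(pmax(out, 0), 1)
}
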