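# Radiometric preprocessing: empirical line calibration from grey reference
# panels and spectral band-position correction by derivative features and
# monotone spline warping.

#' Fit an empirical line calibration from reference panels
#'
#' Per band, ordinary least squares of panel reference reflectance on panel
#' digital number (DN): `reflectance = gain * DN + offset`. For visible
#' bands the fit can be restricted to the `n_darkest` panels by mean
#' reference reflectance (bright-panel saturation rule); NIR bands always
#' use all panels.
#'
#' @param panels Long tibble: `panel_id`, `band`, `dn`,
#'   `reflectance` (reference, 0-1 scale).
#' @param vis_bands Integer band indices treated as visible (e.g.
#'   `sensor$band[sensor$region == "vis"]`), or `NULL` to use all panels
#'   everywhere.
#' @param n_darkest How many darkest panels the visible fit keeps
#'   (default 5); ties in mean reflectance break by panel id.
#' @return Tibble of class `elc_model`: `band`, `gain`, `offset`, `r2`,
#'   `rmse`, `n_panels`.
#' @export
empirical_line_fit <- function(panels, vis_bands = NULL, n_darkest = 5) {
  stopifnot(all(c("panel_id", "band", "dn", "reflectance") %in%
                  names(panels)))
  brightness <- panels |>
    dplyr::group_by(.data$panel_id) |>
    dplyr::summarise(mean_ref = mean(.data$reflectance)) |>
    dplyr::arrange(.data$mean_ref, .data$panel_id)
  darkest <- brightness$panel_id[seq_len(min(n_darkest,
                                             nrow(brightness)))]
  fit_band <- function(df) {
    b <- df$band[1]
    if (!is.null(vis_bands) && b %in% vis_bands) {
      df <- df[df$panel_id %in% darkest, ]
    }
    if (nrow(df) < 2) abort(sprintf("band %s: < 2 panels after subsetting",
                                    b))
    if (var(df$dn) == 0) {
      abort(sprintf("band %s: zero DN variance; line fit undefined", b))
    }
    m <- lm(reflectance ~ dn, data = df)
    res <- df$reflectance - predict(m)
    sst <- sum((df$reflectance - mean(df$reflectance))^2)
    tibble::tibble(
      band = b,
      gain = unname(stats::coef(m)[2]), offset = unname(stats::coef(m)[1]),
      r2 = if (sst == 0) 1 else 1 - sum(res^2) / sst,
      rmse = sqrt(mean(res^2)),
      n_panels = nrow(df)
    )
  }
  out <- panels |>
    dplyr::group_by(.data$band) |>
    dplyr::group_map(~ fit_band(.x |>
                                  dplyr::mutate(band = .y$band[1]))) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$band)
  class(out) <- c("elc_model", class(out))
  out
}

#' Apply an empirical line calibration to DN spectra
#'
#' `reflectance = gain * DN + offset` per band. Values are not clipped;
#' calibration artifacts outside \[0, 1.5\] raise a warning so they can be
#' inspected rather than silently truncated.
#'
#' @param dn Matrix or vector of digital numbers, columns ordered as the
#'   model's bands.
#' @param model [empirical_line_fit()] result.
#' @return Reflectance matrix of the same shape.
#' @export
apply_elc <- function(dn, model) {
  vec <- is.null(dim(dn))
  if (vec) dn <- matrix(dn, nrow = 1)
  if (ncol(dn) != nrow(model)) {
    abort(sprintf("DN has %d bands but the ELC model has %d",
                  ncol(dn), nrow(model)))
  }
  refl <- sweep(sweep(dn, 2, model$gain, `*`), 2, model$offset, `+`)
  if (any(refl < 0 | refl > 1.5)) {
    warn("calibrated reflectance outside [0, 1.5]; check panel fits")
  }
  if (vec) refl[1, ] else refl
}

# Quadratic interpolation of the extremum location around a discrete
# argmax/argmin of y over x (sub-grid precision); NA when on the boundary.
quad_peak <- function(x, y, minimum = FALSE) {
  i <- if (minimum) which.min(y) else which.max(y)
  if (i == 1 || i == length(y)) {
    return(NA_real_)
  }
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) {
    return(x[i])
  }
  x[i] + 0.5 * (y0 - y2) / denom * (x[i + 1] - x[i])
}

# Feature wavelengths of a fine-grid spectrum: green-peak maximum,
# green-to-red descending inflection (argmin of d1), red-edge inflection
# (argmax of d1). Derivatives by central differences.
spectral_features <- function(wavelength, reflectance,
                              windows = list(
                                green_peak = c(500, 600),
                                green_red_inflection = c(550, 680),
                                red_edge_inflection = c(680, 760)
                              )) {
  n <- length(wavelength)
  d1 <- c(NA, (reflectance[3:n] - reflectance[1:(n - 2)]) /
            (wavelength[3:n] - wavelength[1:(n - 2)]), NA)
  in_win <- function(w) wavelength >= w[1] & wavelength <= w[2]
  feats <- c(
    green_peak = {
      i <- which(in_win(windows$green_peak))
      quad_peak(wavelength[i], reflectance[i])
    },
    green_red_inflection = {
      i <- which(in_win(windows$green_red_inflection) & !is.na(d1))
      quad_peak(wavelength[i], d1[i], minimum = TRUE)
    },
    red_edge_inflection = {
      i <- which(in_win(windows$red_edge_inflection) & !is.na(d1))
      quad_peak(wavelength[i], d1[i])
    }
  )
  feats
}

#' Correct spectral band-position shifts against a reference spectrum
#'
#' Locates diagnostic feature wavelengths (green-peak maximum, green-to-red
#' inflection, red-edge inflection) in both spectra from first-derivative
#' extrema, fits a monotone spline through the (sensor feature, reference
#' feature) pairs with identity-pinned grid endpoints, and resamples the
#' spectrum onto the warped wavelength axis by cubic spline. Features whose
#' window holds no interior extremum are skipped with a warning; with no
#' usable feature the input is returned unchanged with a warning.
#'
#' @param wavelength Fine wavelength grid shared by both spectra (nm).
#' @param reflectance Spectrum to correct.
#' @param reference Reference spectrum on the same grid.
#' @return Corrected reflectance vector on `wavelength`.
#' @export
band_shift_correct <- function(wavelength, reflectance, reference) {
  stopifnot(length(wavelength) == length(reflectance),
            length(wavelength) == length(reference))
  if (min(wavelength) > 500 || max(wavelength) < 760) {
    abort("grid must cover the 500-760 nm feature windows")
  }
  f_in <- spectral_features(wavelength, reflectance)
  f_ref <- spectral_features(wavelength, reference)
  ok <- is.finite(f_in) & is.finite(f_ref)
  if (any(!ok)) {
    warn(paste("feature(s) without interior extremum skipped:",
               toString(names(f_in)[!ok])))
  }
  if (!any(ok)) {
    warn("no usable spectral features; returning the input unchanged")
    return(reflectance)
  }
  xs <- c(min(wavelength), f_in[ok], max(wavelength))
  ys <- c(min(wavelength), f_ref[ok], max(wavelength))
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  if (any(diff(ys) <= 0)) {
    warn("feature pairs are not monotone; returning the input unchanged")
    return(reflectance)
  }
  warp <- splinefun(xs, ys, method = "hyman")
  new_axis <- warp(wavelength)
  if (any(diff(new_axis) <= 0)) {
    warn("warp not strictly increasing; returning the input unchanged")
    return(reflectance)
  }
  splinefun(new_axis, reflectance, method = "natural")(wavelength)
}
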