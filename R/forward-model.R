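# Canopy forward model: fixed-parameter ledger and the bundled mini-RTM.
#
# The package's forward-model contract is a function
#   (traits tibble, fixed params, wavelength grid) -> reflectance matrix
# and any PROSPECT/SAIL-class model can be plugged in behind it. The bundled
# model is an analytic stand-in with the qualitative fingerprints of a green
# canopy over soil (red-edge sigmoid, chlorophyll-driven visible absorption,
# structural NIR plateau, linear soil line, gap-fraction mixing); it is a
# numerical fixture, not radiative-transfer physics.

#' Fixed canopy, leaf and soil parameters of the forward model
#'
#' Ledger of the non-retrieved model inputs: leaf water and dry matter,
#' senescent material, leaf inclination (LIDF), hot spot, crown shape (zeta),
#' layer dissociation, brown-area fraction, soil moisture and Hapke soil BRDF
#' coefficients, the Beer-Lambert extinction coefficient `k_ext`, and the
#' sun-view geometry (degrees). The bundled mini-RTM uses `sm` and `k_ext`
#' only and assumes nadir view; the full set is carried as a pass-through for
#' external physical models.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `fixed_canopy_params`.
#' @examples
#' fixed_canopy_params()$sm
#' @export
fixed_canopy_params <- function(...) {
  p <- list(
    cw = 0.0317, cm_dry = 0.005, cs = 0,
    lidfa = 0.66, lidfb = -0.04, hot = 0.05,
    zeta = 1, d_factor = 1, fb = 0, sm = 15,
    hapke_b = 0.84, hapke_c = 0.68, hapke_h = 0.23, hapke_b0 = 0.3,
    k_ext = 0.55,
    tts = 30, tto = 0, psi = 0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) abort(paste("unknown fixed parameter(s):", toString(bad)))
  p <- modifyList(p, dots)
  for (nm in names(p)) check_scalar(p[[nm]], nm)
  structure(p, class = "fixed_canopy_params")
}

#' Constants of the bundled analytic canopy model
#'
#' All coefficients of the mini-RTM, exposed so they can be perturbed in
#' sensitivity checks or replaced wholesale. Soil line: reflectance rises
#' linearly from `soil_base` at 400 nm with slope `soil_slope` per nm,
#' damped by soil moisture (`1 - soil_sm_coef * SM`). Red edge: logistic in
#' wavelength with width `redge_width` nm and inflection
#' `redge_base + redge_lcc_coef * LCC` nm. NIR plateau:
#' `nir_base + nir_struct_coef * (N - 1)`. Visible reflectance: green peak
#' Gaussian at `green_center` (sd `green_width` nm) scaled by
#' `exp(-vis_lcc_coef * LCC)` over a floor `vis_base`.
#'
#' @param ... Named overrides.
#' @return Named list of coefficients.
#' @export
mini_rtm_constants <- function(...) {
  k <- list(
    soil_base = 0.10, soil_slope = 0.25 / 2100, soil_sm_coef = 0.004,
    redge_base = 700, redge_lcc_coef = 0.25, redge_width = 12,
    nir_base = 0.30, nir_struct_coef = 0.08,
    vis_base = 0.04, green_amp = 0.30, green_center = 550, green_width = 35,
    vis_lcc_coef = 0.012,
    grid_min = 400, grid_max = 1000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(k))
  if (length(bad)) abort(paste("unknown mini-RTM constant(s):", toString(bad)))
  modifyList(k, dots)
}

# Soil reflectance spectrum of the mini-RTM (vector over the grid).
mini_rtm_soil <- function(grid, fixed, const = mini_rtm_constants()) {
  (const$soil_base + const$soil_slope * (grid - 400)) *
    (1 - const$soil_sm_coef * fixed$sm)
}

#' Simulate canopy reflectance spectra with the bundled mini-RTM
#'
#' Maps trait combinations to top-of-canopy reflectance on a 1-nm-class
#' wavelength grid. For each row the dense-canopy reflectance is
#' `R_inf = P * S + G * (1 - S)` with red-edge sigmoid `S(lambda)`,
#' NIR plateau `P(N)` and visible term `G(lambda, LCC)`, and the scene mixes
#' canopy and soil by gap fraction: `r = fCover * R_inf + (1 - fCover) * r_s`
#' with `fCover = Cv * (1 - exp(-k_ext * LAI))`. Guarantees: reflectance in
#' (0, 1); NIR reflectance non-decreasing in LAI; red reflectance
#' non-increasing in LCC; bare soil returned exactly when `lai = 0` or
#' `cv = 0`.
#'
#' @param traits Data frame with columns `lai`, `lcc`, `cv`, and optionally
#'   `n_struct` (leaf structure; defaults to 1.5).
#' @param fixed [fixed_canopy_params()] object.
#' @param grid Wavelength grid in nm, within \[400, 1000\].
#' @param const Model coefficients, see [mini_rtm_constants()].
#' @return Matrix of reflectance, `nrow(traits)` x `length(grid)`.
#' @examples
#' r <- simulate_canopy(data.frame(lai = 3, lcc = 65, cv = 0.9),
#'                      grid = 400:1000)
#' range(r)
#' @export
simulate_canopy <- function(traits, fixed = fixed_canopy_params(),
                            grid = 400:1000, const = mini_rtm_constants()) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("lai", "lcc", "cv") %in% names(traits)))
  check_numeric(grid, "grid", lower = const$grid_min, upper = const$grid_max)
  lai <- check_numeric(traits$lai, "traits$lai", lower = 0)
  lcc <- check_numeric(traits$lcc, "traits$lcc", lower = 0)
  cv <- check_numeric(traits$cv, "traits$cv", lower = 0, upper = 1)
  n_struct <- if ("n_struct" %in% names(traits)) traits$n_struct
              else rep(1.5, nrow(traits))
  check_numeric(n_struct, "traits$n_struct", lower = 0)

  n <- nrow(traits)
  w <- length(grid)
  soil <- mini_rtm_soil(grid, fixed, const)

  # n x w sigmoid: red-edge inflection shifts with chlorophyll
  lambda_e <- const$redge_base + const$redge_lcc_coef * lcc
  s <- 1 / (1 + exp(-(outer(-lambda_e, grid, `+`)) / const$redge_width))
  p <- const$nir_base + const$nir_struct_coef * (n_struct - 1)
  g_shape <- const$vis_base +
    const$green_amp * exp(-((grid - const$green_center) / const$green_width)^2)
  # G(lambda, LCC) = vis_base + amp*gauss(lambda)*exp(-c*LCC); split so the
  # wavelength shape and the chlorophyll damping stay vectorized
  g <- outer(exp(-const$vis_lcc_coef * lcc), g_shape - const$vis_base) +
    const$vis_base
  r_inf <- p * s + g * (1 - s)

  fcover <- fcover_from(cv, lai, k = fixed$k_ext)
  r <- fcover * r_inf + outer(1 - fcover, soil)
  dimnames(r) <- NULL
  r
}
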