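# LUT generation: Latin hypercube sampling with Cholesky-imposed trait
# correlation (Iman-Conover), truncated-Gaussian/uniform marginals, and the
# assembly of standard (independent) vs regularized (correlated) LUTs.

#' Prior distributions of the free model variables
#'
#' Default marginals of the retrieved variables, from field measurements and
#' literature: LAI truncated Gaussian N(2.85, 1.17) on \[0.05, 7\] m2/m2;
#' crown cover Cv N(0.71, 0.23) on \[0.05, 1\]; leaf chlorophyll LCC
#' N(65.36, 9.38) on \[40, 90\] ug/cm2; leaf structure N uniform on
#' \[1, 2.5\].
#'
#' @param ... Per-variable overrides as named lists, e.g.
#'   `lai = list(mu = 3)`.
#' @return Tibble with columns `variable`, `law`, `min`, `max`, `mu`,
#'   `sigma`.
#' @examples
#' trait_priors()
#' @export
trait_priors <- function(...) {
  specs <- tibble::tribble(
    ~variable, ~law, ~min, ~max, ~mu, ~sigma,
    "lai", "gaussian", 0.05, 7, 2.85, 1.17,
    "cv", "gaussian", 0.05, 1, 0.71, 0.23,
    "lcc", "gaussian", 40, 90, 65.36, 9.38,
    "n_struct", "uniform", 1, 2.5, NA_real_, NA_real_
  )
  dots <- list(...)
  bad <- setdiff(names(dots), specs$variable)
  if (length(bad)) abort(paste("unknown prior variable(s):", toString(bad)))
  for (v in names(dots)) {
    for (f in names(dots[[v]])) {
      specs[[f]][specs$variable == v] <- dots[[v]][[f]]
    }
  }
  validate_priors(specs)
  specs
}

validate_priors <- function(specs) {
  stopifnot(all(c("variable", "law", "min", "max") %in% names(specs)))
  if (any(specs$min >= specs$max)) abort("prior must have min < max")
  g <- specs$law == "gaussian"
  if (any(g & (!is.finite(specs$mu) | !is.finite(specs$sigma)))) {
    abort("gaussian prior needs finite mu and sigma")
  }
  if (any(g & specs$sigma <= 0)) abort("gaussian prior needs sigma > 0")
  invisible(specs)
}

#' Target correlation model for regularized sampling
#'
#' The measured trait correlation matrix mapped onto the free model
#' variables (LAI -> LAI, fCover -> Cv, CCC -> LCC): r(LAI, Cv) = 0.83,
#' r(LAI, LCC) = 0.97, r(Cv, LCC) = 0.79 by default. The matrix must be
#' symmetric positive definite; its lower Cholesky factor is precomputed.
#'
#' @param r_lai_cv,r_lai_lcc,r_cv_lcc Pairwise Pearson correlations.
#' @param variables Names of the correlated columns, in order.
#' @return List of class `correlation_model` with elements `variables`, `M`
#'   (correlation matrix) and `L` (lower Cholesky factor).
#' @examples
#' trait_correlation()$M
#' @export
trait_correlation <- function(r_lai_cv = 0.83, r_lai_lcc = 0.97,
                              r_cv_lcc = 0.79,
                              variables = c("lai", "cv", "lcc")) {
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- r_lai_cv
  M[1, 3] <- M[3, 1] <- r_lai_lcc
  M[2, 3] <- M[3, 2] <- r_cv_lcc
  dimnames(M) <- list(variables, variables)
  correlation_model(M)
}

#' @rdname trait_correlation
#' @param M Full correlation matrix (symmetric, unit diagonal, positive
#'   definite) with dimnames naming the variables.
#' @export
correlation_model <- function(M) {
  if (!isSymmetric(unname(M), tol = 1e-12)) abort("M must be symmetric")
  if (any(abs(diag(M) - 1) > 1e-12)) abort("M must have unit diagonal")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    minors <- vapply(seq_len(nrow(M)),
                     function(i) det(M[seq_len(i), seq_len(i), drop = FALSE]),
                     numeric(1))
    abort(paste0(
      "M is not positive definite; leading principal minors: ",
      toString(signif(minors, 4))
    ))
  }
  L <- t(chol(M))
  structure(
    list(variables = colnames(M) %||% paste0("v", seq_len(ncol(M))),
         M = M, L = L),
    class = "correlation_model"
  )
}

#' Latin hypercube sample of uniform scores
#'
#' Stratified uniform scores on (0, 1)^d: each column is partitioned into
#' `n` equal-probability strata, one draw is taken per stratum, and rows are
#' permuted independently per column.
#'
#' @param n Number of samples (>= 2).
#' @param d Number of dimensions.
#' @param seed Optional integer seed.
#' @return `n` x `d` matrix of scores in (0, 1).
#' @export
lhs_sample <- function(n, d, seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_scalar(d, "d", lower = 1)
  with_seed(seed, lhs::randomLHS(as.integer(n), as.integer(d)))
}

#' Impose a target correlation on stratified scores
#'
#' Iman-Conover / Cholesky transform. Uniform scores are mapped to normal
#' scores (inverse normal CDF) and exactly standardized per column; with
#' `m` the sample correlation of the scores, `Q = chol_lower(m)` and
#' `L = chol_lower(M)`, the transform `Z1 = Z_scores (L Q^-1)^T` gives a
#' sample whose Pearson correlation equals the target `M` exactly (to
#' numerical precision). Setting `exact = FALSE` applies the literal
#' `Z1 = Z_scores (L Q)^T` variant instead, which only approximates `M`
#' (for LHS scores `m` is close to identity, so the two nearly coincide).
#'
#' @param Z `n` x `d` matrix of uniform scores from [lhs_sample()] (or
#'   normal scores; values outside (0,1) are taken as already normal).
#' @param target [correlation_model()] with `d` variables.
#' @param exact Use the exact `L Q^-1` transform (default `TRUE`).
#' @return `n` x `d` matrix of correlated normal scores, columns named by
#'   the target's variables.
#' @export
impose_correlation <- function(Z, target, exact = TRUE) {
  if (!inherits(target, "correlation_model")) {
    target <- correlation_model(target)
  }
  d <- ncol(target$M)
  if (ncol(Z) != d) abort("Z column count must match the target matrix")
  if (nrow(Z) < d + 1) abort("need at least d + 1 rows to estimate m")
  scores <- if (all(Z > 0 & Z < 1)) qnorm(Z) else Z
  scores <- scale(scores)[, , drop = FALSE] # exact zero mean, unit sd
  m <- cor(scores)
  Q <- t(chol(m))
  if (rcond(Q) < 1e-12) abort("sample score correlation m is singular")
  A <- if (exact) target$L %*% solve(Q) else target$L %*% Q
  Z1 <- scores %*% t(A)
  colnames(Z1) <- target$variables
  Z1
}

# Quantile function of a Gaussian truncated to [lo, hi].
qtruncnorm <- function(p, mu, sigma, lo, hi) {
  p_lo <- pnorm(lo, mu, sigma)
  p_hi <- pnorm(hi, mu, sigma)
  qnorm(p_lo + p * (p_hi - p_lo), mu, sigma)
}

#' Map correlated scores to the target marginal distributions
#'
#' Per column: normal scores -> uniforms via the standard normal CDF ->
#' target marginal via the inverse CDF of the prior (truncated Gaussian or
#' uniform). Monotone maps, so rank correlations are preserved and every
#' output respects its prior's bounds exactly.
#'
#' @param Z1 Score matrix with columns named after variables, e.g. from
#'   [impose_correlation()]; uniform scores in (0,1) are also accepted.
#' @param specs Priors tibble from [trait_priors()]; one row per column of
#'   `Z1`, matched by name.
#' @return Tibble of draws, one column per variable.
#' @export
transform_marginals <- function(Z1, specs) {
  validate_priors(specs)
  vars <- colnames(Z1)
  if (is.null(vars)) {
    if (ncol(Z1) != nrow(specs)) {
      abort("column count must match the number of priors")
    }
    vars <- specs$variable
  }
  missing <- setdiff(vars, specs$variable)
  if (length(missing)) {
    abort(paste("no prior for variable(s):", toString(missing)))
  }
  u <- if (all(Z1 > 0 & Z1 < 1)) Z1 else pnorm(Z1)
  draws <- lapply(seq_along(vars), function(j) {
    s <- specs[specs$variable == vars[j], ]
    if (s$law == "uniform") {
      s$min + u[, j] * (s$max - s$min)
    } else {
      qtruncnorm(u[, j], s$mu, s$sigma, s$min, s$max)
    }
  })
  names(draws) <- vars
  tibble::as_tibble(draws)
}

#' Draw trait samples from the priors
#'
#' One call covering both sampling modes: `mode = "std"` draws each variable
#' independently by LHS; `mode = "reg"` routes the correlated variables
#' through [impose_correlation()] before the marginal transform (variables
#' outside the correlation model stay independent).
#'
#' @param n Number of draws.
#' @param specs Priors from [trait_priors()].
#' @param mode `"std"` (independent) or `"reg"` (correlated).
#' @param corr [trait_correlation()] model (required for `"reg"`).
#' @param seed Optional integer seed.
#' @param exact Passed to [impose_correlation()].
#' @return Tibble of trait draws with derived `fcover` and `ccc` columns
#'   when `lai`, `lcc` and `cv` are all sampled.
#' @export
sample_traits <- function(n, specs = trait_priors(), mode = c("reg", "std"),
                          corr = trait_correlation(), seed = NULL,
                          exact = TRUE) {
  mode <- match.arg(mode)
  validate_priors(specs)
  Z <- lhs_sample(n, nrow(specs), seed = seed)
  colnames(Z) <- specs$variable
  if (mode == "reg") {
    if (is.null(corr)) abort("mode = 'reg' needs a correlation model")
    cvars <- corr$variables
    missing <- setdiff(cvars, specs$variable)
    if (length(missing)) {
      abort(paste("correlated variable(s) missing a prior:",
                  toString(missing)))
    }
    Z1 <- impose_correlation(Z[, cvars, drop = FALSE], corr, exact = exact)
    Z <- cbind(Z1, qnorm(Z[, setdiff(specs$variable, cvars), drop = FALSE]))
  }
  draws <- transform_marginals(Z, specs)
  draws <- draws[, intersect(specs$variable, names(draws))]
  if (all(c("lai", "lcc", "cv") %in% names(draws))) {
    draws <- derive_traits(draws)
  }
  draws
}

#' Build a look-up table of trait samples and simulated band spectra
#'
#' Runs the full LUT pipeline: trait sampling (standard independent or
#' correlation-regularized), forward simulation on a fine wavelength grid,
#' Gaussian resampling to the sensor bands, and noise injection.
#'
#' @param mode `"std"` or `"reg"`.
#' @param n LUT size (default 17280).
#' @param specs,corr Priors and correlation model.
#' @param fixed Fixed canopy parameters.
#' @param forward_model Function `(traits, fixed, grid) -> matrix`; defaults
#'   to [simulate_canopy()].
#' @param sensor Sensor band model.
#' @param grid Fine wavelength grid for the forward model.
#' @param noise_sigma Reflectance noise sd (default 0.005).
#' @param seed Integer seed; trait sampling and noise use derived
#'   substreams.
#' @return Object of class `trait_lut`: list with `traits` (tibble),
#'   `spectra` (n x bands matrix), `sensor`, `mode`, `n`, `noise_sigma`,
#'   `seed`.
#' @examples
#' lut <- build_lut(mode = "reg", n = 100, seed = 1)
#' dim(lut$spectra)
#' @export
build_lut <- function(mode = c("reg", "std"), n = 17280,
                      specs = trait_priors(), corr = trait_correlation(),
                      fixed = fixed_canopy_params(),
                      forward_model = simulate_canopy,
                      sensor = gamaya_sensor(), grid = 400:1000,
                      noise_sigma = 0.005, seed = NULL) {
  mode <- match.arg(mode)
  traits <- sample_traits(n, specs, mode = mode, corr = corr,
                          seed = if (is.null(seed)) NULL
                                 else child_seed(seed, "lut_traits"))
  fine <- forward_model(traits, fixed, grid)
  spectra <- resample_to_sensor(fine, grid, sensor)
  spectra <- add_noise(spectra, sigma = noise_sigma,
                       seed = if (is.null(seed)) NULL
                              else child_seed(seed, "lut_noise"))
  structure(
    list(traits = traits, spectra = spectra, sensor = sensor, mode = mode,
         n = n, noise_sigma = noise_sigma, seed = seed),
    class = "trait_lut"
  )
}

#' @export
print.trait_lut <- function(x, ...) {
  cat(sprintf(
    "<trait_lut> mode=%s  n=%d  bands=%d  noise_sigma=%g  seed=%s\n",
    x$mode, nrow(x$traits), ncol(x$spectra), x$noise_sigma,
    x$seed %||% "none"
  ))
  invisible(x)
}
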