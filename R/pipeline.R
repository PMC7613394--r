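# Orchestration and artifact I/O: one configuration object drives
# campaign simulation, LUT building, inversion, hybrid and in-situ
# retrieval, and evaluation; artifacts round-trip through CSV/JSON.

#' Assemble a full pipeline run configuration
#'
#' Collects every tunable of the four-strategy comparison in one place so a
#' run is reproducible from (config, seed) alone.
#'
#' @param campaign [campaign_config()].
#' @param priors,corr,fixed LUT sampling inputs.
#' @param lut_n LUT size (default 17280).
#' @param noise_sigma LUT spectral noise sd.
#' @param invert_q Best-entry count for LUT inversion.
#' @param hybrid_sizes,hybrid_repeats Hybrid subset ladder and repeats.
#' @param hybrid_lut Which LUT trains the hybrid models (`"reg"` or
#'   `"std"`).
#' @param variables Traits compared across methods.
#' @param seed Root seed; stages derive named substreams.
#' @return List of class `run_config`.
#' @export
run_config <- function(campaign = campaign_config(),
                       priors = trait_priors(),
                       corr = trait_correlation(),
                       fixed = fixed_canopy_params(),
                       lut_n = 17280, noise_sigma = 0.005, invert_q = 300,
                       hybrid_sizes = c(100, 250, 500, 750, 1000, 1500,
                                        2000, 3000, 4000, 5000),
                       hybrid_repeats = 10, hybrid_lut = "reg",
                       variables = c("lai", "fcover", "ccc"), seed = 1) {
  structure(
    list(campaign = campaign, priors = priors, corr = corr, fixed = fixed,
         lut_n = lut_n, noise_sigma = noise_sigma, invert_q = invert_q,
         hybrid_sizes = hybrid_sizes, hybrid_repeats = hybrid_repeats,
         hybrid_lut = hybrid_lut, variables = variables, seed = seed),
    class = "run_config"
  )
}

#' Run the four-strategy retrieval comparison end to end
#'
#' Stages: `campaign` (synthetic plots + spectra), `lut` (standard and
#' regularized LUTs), `invert` (LUT inversion of the plot spectra),
#' `hybrid` (ML on simulations with size selection), `insitu` (RF and
#' RFexp leave-one-date-out), `evaluate` (metrics + tests across methods).
#' Later stages require the artifacts of earlier ones; a stage subset
#' missing its inputs is rejected naming the stage to run first.
#'
#' @param config [run_config()].
#' @param stages Subset of the stage names above, in any order.
#' @param state Optional list of artifacts from a previous partial run.
#' @return List of class `pipeline_run` with the artifacts produced:
#'   `plots`, `lut_std`, `lut_reg`, `estimates` (all methods stacked),
#'   `hybrid`, `report`, plus `config`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("campaign", "lut", "invert", "hybrid",
                                    "insitu", "evaluate"),
                         state = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  need <- function(what, stage, producer) {
    if (is.null(state[[what]])) {
      abort(sprintf("stage '%s' needs artifact '%s'; run stage '%s' first",
                    stage, what, producer))
    }
    state[[what]]
  }

  if ("campaign" %in% stages) {
    plots <- generate_campaign(config$campaign,
                               seed = child_seed(seed, "campaign"))
    state$plots <- generate_spectra(plots, config$campaign,
                                    fixed = config$fixed,
                                    seed = child_seed(seed, "spectra"))
  }
  if ("lut" %in% stages) {
    state$lut_std <- build_lut("std", n = config$lut_n,
                               specs = config$priors, corr = config$corr,
                               fixed = config$fixed,
                               noise_sigma = config$noise_sigma,
                               seed = child_seed(seed, "lut_std"))
    state$lut_reg <- build_lut("reg", n = config$lut_n,
                               specs = config$priors, corr = config$corr,
                               fixed = config$fixed,
                               noise_sigma = config$noise_sigma,
                               seed = child_seed(seed, "lut_reg"))
  }
  if ("invert" %in% stages) {
    plots <- need("plots", "invert", "campaign")
    lut_std <- need("lut_std", "invert", "lut")
    lut_reg <- need("lut_reg", "invert", "lut")
    est_std <- lut_invert(plots, lut_std, q = config$invert_q)
    est_reg <- lut_invert(plots, lut_reg, q = config$invert_q)
    est_std$plot_id <- est_reg$plot_id <- plots$plot_id
    state$est_lut <- dplyr::bind_rows(est_std, est_reg)
  }
  if ("hybrid" %in% stages) {
    plots <- need("plots", "hybrid", "campaign")
    lut <- if (config$hybrid_lut == "reg") {
      need("lut_reg", "hybrid", "lut")
    } else {
      need("lut_std", "hybrid", "lut")
    }
    validation <- dplyr::rename(
      plots,
      lai = "lai_meas", fcover = "fcover_meas", ccc = "ccc_meas",
      lai_true = "lai", fcover_true = "fcover", ccc_true = "ccc"
    )
    state$hybrid <- hybrid_select(
      lut, validation, sizes = config$hybrid_sizes,
      repeats = config$hybrid_repeats, variables = config$variables,
      seed = child_seed(seed, "hybrid")
    )
    state$est_hybrid <- hybrid_predict(state$hybrid, plots)
  }
  if ("insitu" %in% stages) {
    plots <- need("plots", "insitu", "campaign")
    rf_spec <- regressor_spec("rf", seed = child_seed(seed, "insitu"))
    state$est_rf <- insitu_rf_lodo(plots, config$variables,
                                   use_exposure = FALSE, spec = rf_spec)
    state$est_rfexp <- insitu_rf_lodo(plots, config$variables,
                                      use_exposure = TRUE, spec = rf_spec)
  }
  if ("evaluate" %in% stages) {
    plots <- need("plots", "evaluate", "campaign")
    ests <- dplyr::bind_rows(
      state$est_lut, state$est_hybrid, state$est_rf, state$est_rfexp
    )
    if (is.null(ests) || nrow(ests) == 0) {
      abort("stage 'evaluate' needs predictions; run 'invert', 'hybrid' or 'insitu' first")
    }
    meas <- dplyr::rename(
      plots[c("plot_id", "date", "nitrogen",
              paste0(config$variables, "_meas"))],
      !!!setNames(paste0(config$variables, "_meas"), config$variables)
    )
    state$report <- compare_report(ests, meas,
                                   variables = config$variables,
                                   group = "date")
  }
  state$config <- config
  class(state) <- "pipeline_run"
  state
}

#' @export
print.pipeline_run <- function(x, ...) {
  arts <- setdiff(names(x), "config")
  cat("<pipeline_run> artifacts:", toString(arts), "\n")
  invisible(x)
}

#' Apply a trained retrieval model to an image cube
#'
#' Per unmasked pixel, runs a fitted regressor (or a LUT inversion closure)
#' on the pixel spectrum; masked pixels yield `NA`.
#'
#' @param cube 3-D array `rows x cols x bands` of reflectance.
#' @param mask Logical matrix `rows x cols`; `TRUE` pixels are retrieved.
#' @param model A `trait_regressor`, or any function mapping a spectra
#'   matrix to a numeric vector.
#' @return Numeric matrix `rows x cols` of trait estimates with `NA`
#'   outside the mask.
#' @export
map_traits <- function(cube, mask, model) {
  stopifnot(length(dim(cube)) == 3)
  if (!all(dim(mask) == dim(cube)[1:2])) {
    abort("mask dimensions must match the cube")
  }
  nb <- dim(cube)[3]
  out <- matrix(NA_real_, dim(cube)[1], dim(cube)[2])
  idx <- which(mask)
  if (length(idx) == 0) {
    return(out)
  }
  flat <- matrix(cube, ncol = nb)
  X <- flat[idx, , drop = FALSE]
  pred <- if (inherits(model, "trait_regressor")) {
    if (nb != length(model$features)) {
      abort("cube band count does not match the model features")
    }
    predict(model, X)
  } else {
    model(X)
  }
  out[idx] <- pred
  out
}

# ---- Artifact I/O ---------------------------------------------------------

#' Write and read a LUT as a CSV pair with a JSON sidecar
#'
#' `traits.csv` and `spectra.csv` hold the paired tables; `meta.json`
#' records mode, size, noise sigma, seed and the sensor definition, so a
#' reloaded LUT is usable by inversion and hybrid training.
#'
#' @param lut [build_lut()] result.
#' @param dir Directory to create/use.
#' @return `write_lut`: the directory, invisibly. `read_lut`: a
#'   `trait_lut`.
#' @export
write_lut <- function(lut, dir) {
  stopifnot(inherits(lut, "trait_lut"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(lut$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  sp <- as.data.frame(lut$spectra)
  names(sp) <- band_cols(lut$sensor$center)
  utils::write.csv(sp, file.path(dir, "spectra.csv"), row.names = FALSE)
  meta <- list(mode = lut$mode, n = lut$n, noise_sigma = lut$noise_sigma,
               seed = lut$seed,
               sensor = as.data.frame(lut$sensor))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_lut
#' @export
read_lut <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sensor <- tibble::as_tibble(meta$sensor)
  class(sensor) <- c("sensor_model", class(sensor))
  traits <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "traits.csv"))
  )
  spectra <- as.matrix(utils::read.csv(file.path(dir, "spectra.csv")))
  dimnames(spectra) <- NULL
  structure(
    list(traits = traits, spectra = spectra, sensor = sensor,
         mode = meta$mode, n = meta$n, noise_sigma = meta$noise_sigma,
         seed = meta$seed),
    class = "trait_lut"
  )
}

#' Write and read campaign plot tables
#'
#' One row per plot with metadata, trait and `b<center>` spectral columns
#' (the same schema a real-data path would provide).
#'
#' @param plots Campaign tibble.
#' @param path CSV file path.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plots
#' @export
read_plots <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
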