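# Synthetic field campaign: a six-date, three-nitrogen-level potato trial
# with trait trajectories, cross-correlations, illumination/exposure regime
# and measurement noise matching the structure the retrieval comparison
# assumes, so every pipeline stage is testable without field data.

#' Configuration of the synthetic field campaign
#'
#' Defaults reproduce the study design being emulated: six sampling dates
#' (21 plots on the first, 27 on the rest; 156 total), three nitrogen
#' levels (80/180/280 kg/ha) balanced within date, per-date LAI / fCover
#' mean-sd trajectories from the field summary statistics, leaf chlorophyll
#' means derived from the CCC/LAI ratio per date, the measured trait
#' correlation targets, and the per-date illumination class and camera
#' exposure times (seconds).
#'
#' @param nitrogen_effect Monotone shift of the date-level trait mean per
#'   nitrogen step, as a fraction of the date sd (N80 = -1 step,
#'   N180 = 0, N280 = +1 step); default 0.15.
#' @param lai_noise_cv Multiplicative measurement noise CV for LAI
#'   (default 0.08).
#' @param lcc_noise_sd Additive measurement noise sd for LCC, ug/cm2
#'   (default 4).
#' @param fcover_noise_sd Additive noise on visually scored fCover before
#'   rounding to 5% classes (default 0.03).
#' @param gain_classes Illumination gain model per class: mean and sd of a
#'   per-plot multiplicative gain, defaults sunny (1.00, 0.01), partial
#'   (1.00, 0.05), overcast (0.92, 0.04).
#' @param date_gain_share Fraction of gain-class variance shared by all
#'   plots of a date (default 0.5), making exposure time informative about
#'   the perturbation regime.
#' @param spectral_noise_sd Additive per-band sensor noise (default 0.005).
#' @param ... Further overrides of config entries (`dates`, `lcc_sd`, ...).
#' @return List of class `campaign_config`.
#' @examples
#' campaign_config()$dates
#' @export
campaign_config <- function(nitrogen_effect = 0.15, lai_noise_cv = 0.08,
                            lcc_noise_sd = 4, fcover_noise_sd = 0.03,
                            gain_classes = NULL, date_gain_share = 0.5,
                            spectral_noise_sd = 0.005, ...) {
  dates <- tibble::tibble(
    date = c("Jul08", "Jul14", "Jul19", "Jul27", "Aug05", "Aug10"),
    n_plots = c(21L, 27L, 27L, 27L, 27L, 27L),
    illumination = c("partial", "partial", "sunny", "partial",
                     "overcast", "overcast"),
    exposure_vis = 1 / c(840, 840, 840, 496, 328, 328),
    exposure_nir = 1 / c(1135, 1135, 1135, 840, 716, 552),
    sza = c(28, 29, 30, 31, 33, 35),
    lai_mean = c(1.91, 2.19, 2.22, 2.98, 3.94, 3.69),
    lai_sd = c(0.62, 0.91, 0.86, 0.99, 1.05, 0.77),
    fcover_mean = c(0.47, 0.58, 0.62, 0.77, 0.91, 0.88),
    fcover_sd = c(0.17, 0.22, 0.25, 0.14, 0.12, 0.09)
  )
  # leaf chlorophyll trajectory from the canopy-chlorophyll / LAI ratio
  ccc_mean <- c(1.37, 1.48, 1.66, 1.93, 2.27, 2.22)
  dates$lcc_mean <- 100 * ccc_mean / dates$lai_mean
  cfg <- list(
    dates = dates,
    nitrogen_levels = c(80, 180, 280),
    nitrogen_effect = nitrogen_effect,
    lcc_sd = 9.38,
    corr = trait_correlation(),
    bounds = list(lai = c(0.05, 7), cv = c(0.05, 1), lcc = c(40, 90)),
    lai_noise_cv = lai_noise_cv,
    lcc_noise_sd = lcc_noise_sd,
    fcover_noise_sd = fcover_noise_sd,
    gain_classes = gain_classes %||% tibble::tibble(
      illumination = c("sunny", "partial", "overcast"),
      gain_mean = c(1.00, 1.00, 0.92),
      gain_sd = c(0.01, 0.05, 0.04)
    ),
    date_gain_share = date_gain_share,
    spectral_noise_sd = spectral_noise_sd
  )
  cfg <- modifyList(cfg, list(...))
  if (sum(cfg$dates$n_plots) <= 0) abort("campaign needs plots")
  if (any(cfg$gain_classes$gain_mean <= 0)) {
    abort("gain means must be positive")
  }
  structure(cfg, class = "campaign_config")
}

# Balanced nitrogen assignment within a date: counts differ by <= 1.
assign_nitrogen <- function(n, levels) {
  rep(levels, length.out = n)[order(rep(seq_along(levels),
                                        length.out = n))]
}

#' Generate the synthetic campaign plot records (traits only)
#'
#' Per date and nitrogen level, draws correlated (LAI, Cv, LCC) from
#' truncated Gaussians centered on the date trajectory (nitrogen shifts the
#' mean monotonically by `nitrogen_effect` date-sds per step) with the
#' target cross-correlation imposed at score level. Derived fCover/CCC are
#' computed, then measured values add the configured instrument noise;
#' measured fCover is rounded to 5% visual classes and measured CCC is the
#' product of measured LAI and LCC.
#'
#' @param config [campaign_config()].
#' @param seed Integer seed.
#' @return Tibble of plot records: design columns, true traits (`lai`,
#'   `cv`, `lcc`, `fcover`, `ccc`) and measured traits (`*_meas`, plus
#'   `spad_meas`).
#' @export
generate_campaign <- function(config = campaign_config(), seed = 1) {
  stopifnot(inherits(config, "campaign_config"))
  d <- config$dates
  out <- list()
  plot_counter <- 0L
  for (i in seq_len(nrow(d))) {
    n_lv <- assign_nitrogen(d$n_plots[i], config$nitrogen_levels)
    for (lv in unique(n_lv)) {
      n_g <- sum(n_lv == lv)
      step <- match(lv, config$nitrogen_levels) - 2L
      shift <- step * config$nitrogen_effect
      specs <- tibble::tibble(
        variable = c("lai", "cv", "lcc"),
        law = "gaussian",
        min = c(config$bounds$lai[1], config$bounds$cv[1],
                config$bounds$lcc[1]),
        max = c(config$bounds$lai[2], config$bounds$cv[2],
                config$bounds$lcc[2]),
        mu = c(d$lai_mean[i] + shift * d$lai_sd[i],
               d$fcover_mean[i] + shift * d$fcover_sd[i],
               d$lcc_mean[i] + shift * config$lcc_sd),
        sigma = c(d$lai_sd[i], d$fcover_sd[i], config$lcc_sd)
      )
      specs$mu <- pmin(pmax(specs$mu, specs$min), specs$max)
      traits <- sample_traits(
        max(n_g, 4), specs, mode = "reg", corr = config$corr,
        seed = child_seed(seed, sprintf("traits_%d_%s", i, lv))
      )[seq_len(n_g), ]
      grp <- tibble::tibble(
        date = d$date[i], nitrogen = lv,
        illumination = d$illumination[i],
        exposure_vis = d$exposure_vis[i], exposure_nir = d$exposure_nir[i],
        sza = d$sza[i]
      )
      out[[length(out) + 1L]] <- dplyr::bind_cols(grp, traits)
    }
  }
  plots <- dplyr::bind_rows(out)
  plots <- tibble::add_column(
    plots, plot_id = sprintf("p%03d", seq_len(nrow(plots))), .before = 1
  )
  with_seed(child_seed(seed, "measurement"), {
    n <- nrow(plots)
    lai_m <- pmax(plots$lai * (1 + rnorm(n, sd = config$lai_noise_cv)),
                  0.01)
    lcc_m <- pmax(plots$lcc + rnorm(n, sd = config$lcc_noise_sd), 1)
    fc_m <- pmin(pmax(
      plots$fcover + rnorm(n, sd = config$fcover_noise_sd), 0), 1)
    plots$lai_meas <- lai_m
    plots$lcc_meas <- lcc_m
    plots$fcover_meas <- round(fc_m / 0.05) * 0.05
    plots$ccc_meas <- ccc_from(lai_m, lcc_m)
    # SPAD back-computed from measured LCC through the published transfer
    # function; kept as metadata only (non-physical scale, see vignette)
    plots$spad_meas <- lcc_to_spad(lcc_m)
  })
  plots
}

#' Simulate observed spectra for campaign plots
#'
#' True 40-band spectra come from the forward model on the true traits;
#' the observed spectrum multiplies the true spectrum by an illumination
#' gain and adds per-band Gaussian sensor noise. Gains are drawn per plot
#' around the illumination class mean, with a date-level shared component
#' (`date_gain_share` of the class variance), so plots flown on the same
#' date are perturbed coherently.
#'
#' @param plots [generate_campaign()] output.
#' @param config [campaign_config()].
#' @param fixed,forward_model,sensor,grid Forward-model plumbing as in
#'   [build_lut()].
#' @param seed Integer seed.
#' @return `plots` with `gain` and `b<center>` reflectance columns added.
#' @export
generate_spectra <- function(plots, config = campaign_config(),
                             fixed = fixed_canopy_params(),
                             forward_model = simulate_canopy,
                             sensor = gamaya_sensor(), grid = 400:1000,
                             seed = 1) {
  fine <- forward_model(plots[c("lai", "lcc", "cv")], fixed, grid)
  true_sp <- resample_to_sensor(fine, grid, sensor)
  gc <- config$gain_classes
  cls <- match(plots$illumination, gc$illumination)
  if (anyNA(cls)) abort("unknown illumination class in plots")
  share <- config$date_gain_share
  gains <- with_seed(child_seed(seed, "gains"), {
    date_z <- setNames(rnorm(length(unique(plots$date))),
                       unique(plots$date))
    gc$gain_mean[cls] + gc$gain_sd[cls] *
      (sqrt(share) * date_z[plots$date] +
         sqrt(1 - share) * rnorm(nrow(plots)))
  })
  obs <- add_noise(gains * true_sp, sigma = config$spectral_noise_sd,
                   seed = child_seed(seed, "sensor_noise"))
  plots$gain <- as.numeric(gains)
  bind_spectra(plots, obs, sensor$center)
}

#' Generate synthetic calibration panels
#'
#' Nine grey panels with reference reflectance evenly spaced from 0.03 to
#' 0.95, observed as DN through a per-band affine map plus optional noise.
#' With `saturate = TRUE` the brightest panels' DN are clipped at the
#' saturation level and flagged, exercising the darkest-panel selection
#' rule of the visible-camera calibration.
#'
#' @param sensor Sensor band model.
#' @param n_panels Number of panels (default 9).
#' @param gain,offset True DN-per-reflectance gain and dark offset of the
#'   affine map.
#' @param dn_noise_sd Additive DN noise (default 0, i.e. noiseless).
#' @param saturate Clip DN above `sat_level`.
#' @param sat_level DN saturation ceiling.
#' @param seed Integer seed.
#' @return Long tibble: `panel_id`, `band`, `dn`, `reflectance`,
#'   `saturated`.
#' @export
generate_panels <- function(sensor = gamaya_sensor(), n_panels = 9,
                            gain = 2000, offset = 100, dn_noise_sd = 0,
                            saturate = FALSE, sat_level = 1600,
                            seed = 1) {
  refl <- seq(0.03, 0.95, length.out = n_panels)
  grid <- tidyr::expand_grid(
    panel_id = sprintf("panel%02d", seq_len(n_panels)),
    band = sensor$band
  )
  grid$reflectance <- rep(refl, each = nrow(sensor))
  dn <- gain * grid$reflectance + offset
  if (dn_noise_sd > 0) {
    dn <- dn + with_seed(child_seed(seed, "panel_noise"),
                         rnorm(length(dn), sd = dn_noise_sd))
  }
  grid$saturated <- FALSE
  if (saturate) {
    grid$saturated <- dn > sat_level
    dn <- pmin(dn, sat_level)
  }
  grid$dn <- dn
  grid[c("panel_id", "band", "dn", "reflectance", "saturated")]
}
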