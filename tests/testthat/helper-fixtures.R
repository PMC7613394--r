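# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Synthetic campaign with observed spectra under default study conditions.
fixture_campaign <- function(seed = 1) {
  memo(paste0("campaign_", seed), {
    cfg <- campaign_config()
    plots <- generate_campaign(cfg, seed = seed)
    generate_spectra(plots, cfg, seed = seed)
  })
}

# Small noise-free LUT for exact-retrieval checks.
fixture_lut_clean <- function() {
  memo("lut_clean", build_lut("reg", n = 400, noise_sigma = 0, seed = 11))
}

# Moderate regularized LUT for retrieval accuracy checks.
fixture_lut_reg <- function() {
  memo("lut_reg", build_lut("reg", n = 3000, seed = 21))
}

fixture_lut_std <- function() {
  memo("lut_std", build_lut("std", n = 3000, seed = 21))
}

# Measured-trait table in evaluation layout.
measured_table <- function(plots) {
  tibble::tibble(plot_id = plots$plot_id, date = plots$date,
                 nitrogen = plots$nitrogen, lai = plots$lai_meas,
                 fcover = plots$fcover_meas, ccc = plots$ccc_meas)
}
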