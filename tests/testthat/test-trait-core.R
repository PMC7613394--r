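# Trait formulas, forward model, sensor resampling, noise injection.

test_that("SPAD conversion follows the exponential transfer function", {
  expect_equal(spad_to_lcc(0), 0.0913)
  expect_equal(spad_to_lcc(50), 0.0913 * exp(0.0415 * 50), tolerance = 1e-12)
  expect_equal(spad_to_lcc(50), 0.7272, tolerance = 1e-4)
  expect_gt(spad_to_lcc(60), spad_to_lcc(50))
  expect_error(spad_to_lcc(-1), "outside")
  expect_error(spad_to_lcc(NaN), "finite")
})

test_that("fCover gap-fraction formula behaves across its domain", {
  expect_equal(fcover_from(0.9, 0), 0)
  expect_equal(fcover_from(0.71, 2.85, k = 0.55), 0.5619, tolerance = 1e-4)
  expect_equal(fcover_from(1, 1000), 1.0, tolerance = 1e-12)
  # bounded by cv and increasing in lai
  lai <- seq(0, 8, by = 0.5)
  fc <- fcover_from(0.8, lai)
  expect_true(all(fc <= 0.8 + 1e-15))
  expect_true(all(diff(fc) > 0))
  expect_error(fcover_from(1.2, 1), "outside")
})

test_that("CCC is the unit-converted LAI x LCC product", {
  expect_equal(ccc_from(0, 65), 0)
  expect_equal(ccc_from(2.85, 65.36), 1.8628, tolerance = 1e-4)
  expect_equal(ccc_from(2.04, 70.588), 1.44, tolerance = 1e-3)
  expect_error(ccc_from(-1, 65), "finite|outside")
})

test_that("trait formulas match brute-force evaluation on random inputs", {
  set.seed(42)
  n <- 1000
  spad <- runif(n, 0, 80)
  cv <- runif(n)
  lai <- runif(n, 0, 7)
  lcc <- runif(n, 20, 100)
  # independent oracle: element-by-element loop on the printed formulas
  for (i in sample(n, 50)) {
    expect_equal(spad_to_lcc(spad[i]), 0.0913 * exp(0.0415 * spad[i]),
                 tolerance = 1e-10)
    expect_equal(fcover_from(cv[i], lai[i]),
                 cv[i] * (1 - exp(-0.55 * lai[i])), tolerance = 1e-10)
    expect_equal(ccc_from(lai[i], lcc[i]), 0.01 * lai[i] * lcc[i],
                 tolerance = 1e-10)
  }
})

test_that("fixed-parameter ledger carries the documented defaults", {
  p <- fixed_canopy_params()
  expect_equal(p$cw, 0.0317)
  expect_equal(p$cm_dry, 0.005)
  expect_equal(p$cs, 0)
  expect_equal(c(p$lidfa, p$lidfb), c(0.66, -0.04))
  expect_equal(p$hot, 0.05)
  expect_equal(c(p$zeta, p$d_factor, p$fb, p$sm), c(1, 1, 0, 15))
  expect_equal(c(p$hapke_b, p$hapke_c, p$hapke_h, p$hapke_b0),
               c(0.84, 0.68, 0.23, 0.3))
  expect_equal(p$k_ext, 0.55)
  expect_error(fixed_canopy_params(bogus = 1), "unknown")
})

test_that("mini-RTM honors its stated guarantees", {
  grid <- 400:1000
  # bare soil when lai = 0 or cv = 0
  fixed <- fixed_canopy_params()
  soil <- lutraits:::mini_rtm_soil(grid, fixed)
  r0 <- simulate_canopy(data.frame(lai = 0, lcc = 65, cv = 0.5),
                        fixed, grid)
  expect_equal(as.numeric(r0), soil, tolerance = 1e-14)
  r0b <- simulate_canopy(data.frame(lai = 3, lcc = 65, cv = 0), fixed, grid)
  expect_equal(as.numeric(r0b), soil, tolerance = 1e-14)

  # closed-form dense-canopy limit at 850 nm
  k <- mini_rtm_constants()
  r7 <- simulate_canopy(data.frame(lai = 7, lcc = 65, cv = 1,
                                   n_struct = 1.5), fixed, grid)
  s850 <- 1 / (1 + exp(-(850 - (700 + 0.25 * 65)) / 12))
  g850 <- 0.04 + 0.30 * exp(-((850 - 550) / 35)^2) * exp(-0.012 * 65)
  p850 <- 0.30 + 0.08 * (1.5 - 1)
  r_inf <- p850 * s850 + g850 * (1 - s850)
  fc <- 1 - exp(-0.55 * 7)
  expect_equal(r7[1, which(grid == 850)],
               fc * r_inf + (1 - fc) * soil[which(grid == 850)],
               tolerance = 1e-12)
  expect_equal(r7[1, which(grid == 850)], r_inf, tolerance = 2e-2)

  # monotonicity: LCC darkens the red, LAI brightens the NIR
  two <- simulate_canopy(data.frame(lai = c(3, 3), lcc = c(40, 90),
                                    cv = c(0.9, 0.9)), fixed, grid)
  expect_lt(two[2, which(grid == 672)], two[1, which(grid == 672)])
  two2 <- simulate_canopy(data.frame(lai = c(1, 5), lcc = c(65, 65),
                                     cv = c(0.9, 0.9)), fixed, grid)
  expect_gte(two2[2, which(grid == 850)], two2[1, which(grid == 850)])

  # physical range and input validation
  set.seed(7)
  rnd <- simulate_canopy(data.frame(lai = runif(20, 0, 7),
                                    lcc = runif(20, 40, 90),
                                    cv = runif(20, 0.05, 1)), fixed, grid)
  expect_true(all(rnd > 0 & rnd < 1))
  expect_error(simulate_canopy(data.frame(lai = 3, lcc = 65, cv = 0.5),
                               fixed, grid = 300:500), "outside")
  expect_error(simulate_canopy(data.frame(lai = NA, lcc = 65, cv = 0.5),
                               fixed, grid), "finite")
})

test_that("gap-fraction mixing is algebraically consistent", {
  # Cv * [beta * R_inf + (1 - beta) * r_s] + (1 - Cv) * r_s must equal
  # fCover * R_inf + (1 - fCover) * r_s with beta = 1 - exp(-k lai)
  grid <- seq(420, 950, by = 5)
  fixed <- fixed_canopy_params()
  soil <- lutraits:::mini_rtm_soil(grid, fixed)
  set.seed(3)
  for (i in 1:25) {
    cv <- runif(1)
    lai <- runif(1, 0, 7)
    lcc <- runif(1, 40, 90)
    beta <- 1 - exp(-0.55 * lai)
    r <- simulate_canopy(data.frame(lai = lai, lcc = lcc, cv = cv),
                         fixed, grid)
    r_dense <- simulate_canopy(data.frame(lai = 50, lcc = lcc, cv = 1),
                               fixed, grid)
    # recover R_inf from the dense run (fCover -> 1), then remix
    mix <- cv * (beta * r_dense + (1 - beta) * rep(soil, each = 1)) +
      (1 - cv) * rep(soil, each = 1)
    expect_equal(as.numeric(r), as.numeric(mix), tolerance = 1e-10)
  }
})

test_that("sensor layout matches the two-camera 40-band construction", {
  s <- gamaya_sensor()
  expect_s3_class(s, "sensor_model")
  expect_equal(nrow(s), 40)
  expect_false(is.unsorted(s$center))
  expect_true(all(s$fwhm >= 15 & s$fwhm <= 27))
  expect_equal(range(s$center[s$region == "vis"]), c(474, 638))
  expect_equal(sum(s$region == "vis"), 25)
  expect_equal(sum(s$region == "nir"), 15)
  # overlapping cameras: 638 appears in both
  expect_equal(sum(s$center == 638), 2)
  # without dropping, the 41st band would sit at 915
  full <- gamaya_sensor(drop_last = FALSE)
  expect_equal(nrow(full), 41)
  expect_equal(full$center[41], 915)
})

test_that("Gaussian band resampling preserves constants and linear ramps", {
  s <- gamaya_sensor()
  grid <- 400:1000
  flat <- matrix(0.3, 2, length(grid))
  out <- resample_to_sensor(flat, grid, s)
  expect_equal(dim(out), c(2, 40))
  expect_equal(as.numeric(out), rep(0.3, 80), tolerance = 1e-10)
  # linear ramp maps to the band centers (symmetric weights)
  a <- 0.02; b <- 4e-4
  ramp <- a + b * grid
  out2 <- resample_to_sensor(ramp, grid, s)
  expect_equal(as.numeric(out2), a + b * s$center, tolerance = 1e-6)
  expect_error(resample_to_sensor(matrix(0.3, 1, 101), 500:600, s),
               "band")
})

test_that("noise injection is seeded, scaled and clipped", {
  s <- matrix(runif(10000, 0.2, 0.8), 1)
  expect_identical(add_noise(s, sigma = 0), s)
  n1 <- add_noise(s, sigma = 0.005, seed = 9)
  n2 <- add_noise(s, sigma = 0.005, seed = 9)
  expect_identical(n1, n2)
  # sample sd of the perturbation within chi-square bounds at 10,000 bands
  dev <- as.numeric(n1 - s)
  expect_gt(sd(dev), 0.0045)
  expect_lt(sd(dev), 0.0055)
  # multiplicative mode scales with the signal
  nm <- add_noise(matrix(0.5, 1, 5000), sigma = 0.01,
                  mode = "multiplicative", seed = 1)
  expect_equal(sd(nm - 0.5), 0.005, tolerance = 0.1)
  # clipping keeps reflectance physical
  hi <- add_noise(matrix(1, 1, 1000), sigma = 0.05, seed = 2)
  expect_true(all(hi <= 1))
})
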