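# Regressors, hybrid size/method selection, leave-one-date-out retrieval.

make_linear_fixture <- function(n = 500, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  j <- min(4, p)
  list(X = X, y = 3 * X[, j] + rnorm(n, sd = 0.01))
}

test_that("all regressors handle constant targets and recover linear signal", {
  fx <- make_linear_fixture()
  tr <- 1:400; te <- 401:500
  for (m in c("rf", "gpr", "ccf")) {
    const <- train_regressor(fx$X[tr, ], rep(5, 400), regressor_spec(m))
    expect_equal(predict(const, fx$X[te, ]), rep(5, 100), tolerance = 1e-8)
    mod <- train_regressor(fx$X[tr, ], fx$y[tr],
                           regressor_spec(m, seed = 1))
    r2 <- cor(predict(mod, fx$X[te, ]), fx$y[te])^2
    expect_gt(r2, 0.95)
  }
  expect_error(train_regressor(fx$X[1:5, ], fx$y[1:5],
                               regressor_spec("rf")), "10")
})

test_that("GPR predictive sd rises away from the training support", {
  fx <- make_linear_fixture(n = 200, p = 3)
  mod <- train_regressor(fx$X, fx$y, regressor_spec("gpr"))
  near <- fx$X[1, , drop = FALSE]
  far <- near + 10
  ps <- predict(mod, rbind(near, far), se = TRUE)
  expect_lt(ps$se[1], ps$se[2])
  expect_error(predict(train_regressor(fx$X, fx$y, regressor_spec("rf")),
                       fx$X, se = TRUE), "GPR")
})

test_that("regressors are deterministic under a fixed seed", {
  fx <- make_linear_fixture(n = 120, p = 5)
  for (m in c("rf", "ccf")) {
    m1 <- train_regressor(fx$X, fx$y, regressor_spec(m, seed = 7))
    m2 <- train_regressor(fx$X, fx$y, regressor_spec(m, seed = 7))
    expect_identical(predict(m1, fx$X), predict(m2, fx$X))
  }
  g1 <- train_regressor(fx$X, fx$y, regressor_spec("gpr", seed = 7))
  g2 <- train_regressor(fx$X, fx$y, regressor_spec("gpr", seed = 7))
  expect_identical(predict(g1, fx$X), predict(g2, fx$X))
})

test_that("regressors beat the mean-predictor baseline on smooth spectra", {
  lut <- build_lut("reg", n = 1000, seed = 77)
  tr <- 1:800; te <- 801:1000
  base_nrmse <- retrieval_metrics(
    lut$traits$lai[te], rep(mean(lut$traits$lai[tr]), 200)
  )$nrmse_pct
  for (m in c("rf", "gpr", "ccf")) {
    spec <- regressor_spec(m, seed = 3,
                           trees = if (m == "rf") 150 else 30)
    mod <- train_regressor(lut$spectra[tr, ], lut$traits$lai[tr], spec)
    nr <- retrieval_metrics(lut$traits$lai[te],
                            predict(mod, lut$spectra[te, ]))$nrmse_pct
    expect_lt(nr, base_nrmse)
  }
})

test_that("hybrid selection fills the score grid and picks the best NRMSE", {
  lut <- fixture_lut_reg()
  plots <- fixture_campaign(1)
  val <- dplyr::bind_cols(
    plots[c("plot_id")],
    tibble::tibble(lai = plots$lai_meas, fcover = plots$fcover_meas,
                   ccc = plots$ccc_meas),
    plots[grep("^b[0-9]", names(plots))]
  )
  methods <- list(rf = regressor_spec("rf", trees = 100),
                  ccf = regressor_spec("ccf", trees = 20))
  hs <- hybrid_select(lut, val, sizes = c(100, 300), repeats = 2,
                      methods = methods, variables = c("lai", "fcover"),
                      seed = 4)
  expect_equal(nrow(hs$scores), 2 * 2 * 2) # methods x sizes x variables
  for (v in c("lai", "fcover")) {
    sub <- hs$scores[hs$scores$variable == v, ]
    pick <- hs$chosen[hs$chosen$variable == v, ]
    expect_equal(pick$nrmse_pct, min(sub$nrmse_pct))
  }
  # single method, single size trivially selected
  hs1 <- hybrid_select(lut, val, sizes = 100, repeats = 1,
                       methods = methods["rf"], variables = "lai",
                       seed = 4)
  expect_equal(hs1$chosen$method, "rf")
  expect_equal(hs1$chosen$size, 100)
  pred <- hybrid_predict(hs1, plots)
  expect_equal(nrow(pred), nrow(plots))
  expect_error(hybrid_select(lut, val, sizes = 1e6), "exceeds")
})

test_that("hybrid learning curves do not degrade from small to large subsets", {
  # noise-free validation drawn from the same forward model
  lut <- fixture_lut_reg()
  holdout <- build_lut("reg", n = 120, noise_sigma = 0, seed = 88)
  val <- bind_spectra(
    tibble::tibble(plot_id = sprintf("v%03d", 1:120),
                   lai = holdout$traits$lai),
    holdout$spectra, holdout$sensor$center
  )
  ok <- 0
  for (s in 1:5) {
    hs <- hybrid_select(lut, val, sizes = c(100, 1000), repeats = 2,
                        methods = list(rf = regressor_spec("rf",
                                                           trees = 100)),
                        variables = "lai", seed = s)
    nr <- hs$scores$nrmse_pct[order(hs$scores$size)]
    ok <- ok + (nr[2] <= nr[1] * 1.2) # no >20% relative increase
  }
  expect_gte(ok, 3)
})

test_that("leave-one-date-out partitions cleanly and never leaks", {
  plots <- fixture_campaign(1)
  rf <- insitu_rf_lodo(plots, spec = regressor_spec("rf", trees = 100,
                                                    seed = 2))
  expect_equal(nrow(rf), nrow(plots))
  expect_setequal(rf$plot_id, plots$plot_id)
  expect_equal(rf$plot_id, plots$plot_id) # aligned
  # training sizes: 156 minus the held-out date
  per_date <- table(plots$date)
  for (d in names(per_date)) {
    expect_equal(unique(rf$train_n[rf$date == d]),
                 nrow(plots) - per_date[[d]])
  }
  expect_equal(sort(unique(rf$train_n)), c(129, 135))
  expect_equal(unique(rf$method), "RF")
  expect_error(insitu_rf_lodo(plots[plots$date == "Jul08", ]), "dates")
})

test_that("a constant exposure covariate leaves RF predictions centred together", {
  plots <- fixture_campaign(1)
  plots$exposure_vis <- 0.002
  plots$exposure_nir <- 0.001
  rf <- insitu_rf_lodo(plots, variables = "lai",
                       spec = regressor_spec("rf", trees = 150, seed = 3))
  rfe <- insitu_rf_lodo(plots, variables = "lai", use_exposure = TRUE,
                        spec = regressor_spec("rf", trees = 150, seed = 3))
  d <- rf$lai - rfe$lai
  # paired differences centred on zero
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 0.02)
})

test_that("exposure covariate helps under date-level illumination drift", {
  wins <- 0
  for (s in 1:5) {
    plots <- fixture_campaign(s)
    rf <- insitu_rf_lodo(plots, variables = "lai",
                         spec = regressor_spec("rf", trees = 300,
                                               seed = s))
    rfe <- insitu_rf_lodo(plots, variables = "lai", use_exposure = TRUE,
                          spec = regressor_spec("rf", trees = 300,
                                                seed = s))
    n1 <- retrieval_metrics(plots$lai_meas, rf$lai)$nrmse_pct
    n2 <- retrieval_metrics(plots$lai_meas, rfe$lai)$nrmse_pct
    wins <- wins + (n2 <= n1)
  }
  expect_gte(wins, 4)
})
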