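# Metrics, Friedman test, post-hoc adjustment, paired t, report assembly.

test_that("metrics match their definitions and a naive oracle", {
  m <- retrieval_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$nrmse_pct, 0)
  # NRMSE arithmetic: rmse 0.5 over range 5 -> 10%
  obs <- c(0, 5); pred <- obs + 0.5
  expect_equal(retrieval_metrics(obs, pred)$nrmse_pct, 10)
  set.seed(20)
  o <- runif(50); p <- o + rnorm(50, sd = 0.1)
  m2 <- retrieval_metrics(o, p)
  sq <- 0
  for (i in 1:50) sq <- sq + (o[i] - p[i])^2
  expect_equal(m2$rmse, sqrt(sq / 50), tolerance = 1e-12)
  expect_equal(m2$nrmse_pct, 100 * m2$rmse / (max(o) - min(o)),
               tolerance = 1e-12)
  expect_equal(m2$r2, cor(o, p)^2, tolerance = 1e-12)
  # sum-of-squares variant on request
  m3 <- retrieval_metrics(o, p, r2 = "ss")
  expect_equal(m3$r2, 1 - sq / sum((o - mean(o))^2), tolerance = 1e-12)
  expect_error(retrieval_metrics(c(1, 1), c(1, 2)), "range")
})

test_that("Friedman statistic matches hand computation and base R", {
  # consistent ranking fixture: every block orders methods 1 < 2 < 3
  err <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE)
  fr <- friedman_rank_test(err)
  expect_equal(fr$statistic, 10.0)
  expect_equal(fr$df, 2)
  # identical columns: statistic 0, p 1
  tied <- matrix(1, 4, 3)
  fr0 <- friedman_rank_test(tied)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)
  # untied random data agrees with stats::friedman.test
  set.seed(31)
  e <- matrix(rnorm(8 * 4), 8, 4)
  fr1 <- friedman_rank_test(e)
  bf <- stats::friedman.test(e)
  expect_equal(fr1$statistic, unname(bf$statistic), tolerance = 1e-12)
  expect_equal(fr1$p_value, bf$p.value, tolerance = 1e-12)
})

test_that("chi-square p approximates the exact permutation distribution", {
  # exhaustive oracle: all (3!)^4 equally likely within-block rankings
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  6, 3, byrow = TRUE)
  stat_of <- function(R) {
    n <- nrow(R); k <- ncol(R)
    12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  }
  grid <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(grid, 1, function(ii) {
    stat_of(perms[unlist(ii), , drop = FALSE])
  })
  err <- matrix(c(1, 2, 3, 1.5, 2.5, 2, 2, 3, 4, 1, 1.5, 2.5),
                4, 3, byrow = TRUE)
  fr <- friedman_rank_test(err)
  p_exact <- mean(stats_all >= fr$statistic - 1e-9)
  expect_lt(abs(fr$p_value - p_exact), 0.02)
})

test_that("Friedman statistic is invariant to monotone within-block maps", {
  set.seed(17)
  e <- matrix(runif(6 * 3, 0.1, 2), 6, 3)
  base <- friedman_rank_test(e)$statistic
  expect_equal(friedman_rank_test(exp(e))$statistic, base)
  expect_equal(friedman_rank_test(e^3)$statistic, base)
  # different monotone map per block is also allowed (rank-based)
  e2 <- sweep(e, 1, apply(e, 1, max), `/`)
  expect_equal(friedman_rank_test(e2)$statistic, base)
})

test_that("post-hoc adjustment obeys the dominance relations", {
  set.seed(23)
  e <- matrix(rnorm(12 * 3), 12, 3)
  e[, 1] <- e[, 1] + 1.2
  colnames(e) <- c("a", "b", "c")
  ph <- pairwise_posthoc(e)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  bonf <- pmin(1, ph$p_raw * 3)
  expect_true(all(ph$p_adj <= bonf + 1e-12))
  # k = 2: adjusted equals raw
  ph2 <- pairwise_posthoc(e[, 1:2])
  expect_equal(ph2$p_adj, ph2$p_raw)
  # all-identical columns: everything 1
  tied <- matrix(1, 5, 3)
  expect_true(all(pairwise_posthoc(tied)$p_adj == 1))
  # exhaustive enumeration refused for large k without fallback
  e6 <- matrix(rnorm(10 * 6), 10, 6)
  expect_error(pairwise_posthoc(e6), "holm")
  expect_s3_class(pairwise_posthoc(e6, procedure = "holm"), "tbl_df")
})

test_that("paired t-test matches the hand-computed fixture", {
  b <- c(0, 0, 0, 0)
  a <- c(1, 0, -1, 2)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, 0.7746, tolerance = 1e-3)
  expect_equal(tt$df, 3)
  # antisymmetry
  tt2 <- paired_ttest(b, a)
  expect_equal(tt2$t, -tt$t)
  expect_equal(tt2$p_value, tt$p_value)
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "variance")
})

test_that("evaluation report has the method x variable x group layout", {
  plots <- fixture_campaign(1)
  meas <- measured_table(plots)
  set.seed(5)
  fake_est <- function(method, noise) {
    tibble::tibble(
      plot_id = meas$plot_id, method = method,
      lai = meas$lai + rnorm(156, sd = noise),
      fcover = pmin(pmax(meas$fcover + rnorm(156, sd = noise / 4), 0), 1),
      ccc = meas$ccc + rnorm(156, sd = noise / 2)
    )
  }
  ests <- dplyr::bind_rows(
    fake_est("hybrid", 0.6), fake_est("LUTreg", 0.4),
    fake_est("RF", 0.3), fake_est("RFexp", 0.25),
    dplyr::mutate(fake_est("LUTstd", 0.5))
  )
  rep <- compare_report(ests, meas, group = "date")
  # 5 methods x 3 variables x (6 dates + pooled)
  expect_equal(nrow(rep$metrics), 5 * 3 * 7)
  expect_true(all(c("pooled", unique(as.character(meas$date))) %in%
                    rep$metrics$group))
  # NRMSE identity holds on every emitted row
  expect_equal(rep$metrics$nrmse_pct,
               100 * rep$metrics$rmse / rep$metrics$range_used,
               tolerance = 1e-10)
  # Friedman + posthoc present for >= 3 methods; t-test for the LUT pair
  expect_equal(nrow(rep$friedman), 3)
  expect_equal(nrow(rep$posthoc), 3 * choose(5, 2))
  expect_true(all(rep$ttests$pair == "LUTstd vs LUTreg"))
  # order invariance
  perm <- sample(nrow(ests))
  rep2 <- compare_report(ests[perm, ], meas, group = "date")
  expect_equal(rep2$metrics, rep$metrics)
  # single method, single date: metrics only
  one <- fake_est("RF", 0.3)[meas$date == "Jul08", ]
  rep1 <- compare_report(one, meas[meas$date == "Jul08", ], group = NULL)
  expect_equal(nrow(rep1$metrics), 3)
  expect_null(rep1$friedman)
  # tidy/glance accessors
  expect_s3_class(tidy(rep, "metrics"), "tbl_df")
  expect_equal(glance(rep)$methods, 5)
})
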