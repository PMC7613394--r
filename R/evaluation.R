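# Accuracy metrics and significance testing across retrieval methods.

#' Retrieval accuracy metrics
#'
#' R^2 (squared Pearson correlation by default, retrieval-literature
#' convention), RMSE in trait units, and NRMSE% = 100 * RMSE / range of the
#' measured variable within the evaluated group.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2);
#'   `observed` must have a non-zero range.
#' @param r2 `"correlation"` (squared Pearson r) or `"ss"`
#'   (1 - SS_res/SS_tot).
#' @return One-row tibble: `r2`, `rmse`, `nrmse_pct`, `n`, `range_used`.
#' @examples
#' retrieval_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
retrieval_metrics <- function(observed, predicted,
                              r2 = c("correlation", "ss")) {
  r2 <- match.arg(r2)
  check_numeric(observed, "observed")
  check_numeric(predicted, "predicted")
  n <- length(observed)
  if (length(predicted) != n || n < 2) {
    abort("observed and predicted must have equal length >= 2")
  }
  rng <- max(observed) - min(observed)
  if (rng <= 0) abort("observed range is zero; NRMSE undefined")
  rmse <- sqrt(mean((observed - predicted)^2))
  r2v <- if (r2 == "correlation") {
    if (sd(predicted) == 0 || sd(observed) == 0) NA_real_
    else cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  tibble::tibble(r2 = r2v, rmse = rmse, nrmse_pct = 100 * rmse / rng,
                 n = n, range_used = rng)
}

# Mid-ranks within each row (block).
block_ranks <- function(errors) {
  t(apply(errors, 1, rank))
}

#' Friedman rank test across methods
#'
#' Nonparametric test of whether `k` methods differ, from `n` blocks
#' (e.g. plots) of per-method errors. Uses within-block mid-ranks and the
#' tie-corrected chi-square statistic with `k - 1` degrees of freedom;
#' columns identical in every block give statistic 0, p = 1.
#'
#' @param errors Numeric matrix, blocks x methods.
#' @return Tibble: `statistic`, `df`, `p_value`, `n_blocks`, `k_methods`,
#'   plus a `mean_ranks` list-column.
#' @export
friedman_rank_test <- function(errors) {
  errors <- as.matrix(errors)
  n <- nrow(errors)
  k <- ncol(errors)
  if (n < 2 || k < 2) abort("need >= 2 blocks and >= 2 methods")
  R <- block_ranks(errors)
  colsum <- colSums(R)
  # Tie-corrected statistic: (k-1) * SS_treatment / SS_total of the ranks
  ss_t <- sum((colsum - n * (k + 1) / 2)^2) / n
  ss_tot <- sum((R - (k + 1) / 2)^2)
  if (ss_tot == 0) {
    stat <- 0
  } else {
    stat <- n * (k - 1) * ss_t / ss_tot
  }
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = k - 1, p_value = p,
                 n_blocks = n, k_methods = k,
                 mean_ranks = list(colsum / n))
}

# All set partitions of 1..k (restricted growth strings).
set_partitions <- function(k) {
  out <- list()
  recurse <- function(assign, next_block) {
    i <- length(assign) + 1
    if (i > k) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (b in seq_len(next_block)) {
      recurse(c(assign, b), max(next_block, b + 1))
    }
  }
  recurse(integer(0), 1)
  out
}

# Exhaustive hypothesis sets for pairwise equality hypotheses on k methods:
# one per set partition, the pairs lying within a common block.
exhaustive_sets <- function(k, pairs) {
  parts <- set_partitions(k)
  sets <- lapply(parts, function(assign) {
    which(assign[pairs[, 1]] == assign[pairs[, 2]])
  })
  sets <- unique(sets[lengths(sets) > 0])
  sets
}

#' Pairwise post-hoc comparison after a Friedman test
#'
#' Pairwise z-statistics from mean-rank differences,
#' `z = (R_i - R_j) / sqrt(k (k + 1) / (6 n))`, with raw two-sided normal
#' p-values adjusted by the Bergmann-Hommel exhaustive-set procedure
#' (`APV_i = max over exhaustive sets I containing i of |I| * min p_I`,
#' capped at 1) for `k <= max_exhaustive_k`, or Holm otherwise.
#'
#' @param errors Blocks x methods error matrix (column names label the
#'   methods).
#' @param procedure `"bergmann_hommel"` or `"holm"`.
#' @param max_exhaustive_k Largest `k` for which exhaustive sets are
#'   enumerated (default 4); larger `k` with `procedure =
#'   "bergmann_hommel"` is rejected with guidance to use Holm.
#' @return Tibble: `method_a`, `method_b`, `z`, `p_raw`, `p_adj`,
#'   `procedure`.
#' @export
pairwise_posthoc <- function(errors,
                             procedure = c("bergmann_hommel", "holm"),
                             max_exhaustive_k = 4) {
  procedure <- match.arg(procedure)
  errors <- as.matrix(errors)
  n <- nrow(errors)
  k <- ncol(errors)
  if (k < 2) abort("need >= 2 methods")
  methods <- colnames(errors) %||% paste0("m", seq_len(k))
  R <- colMeans(block_ranks(errors))
  pairs <- t(utils::combn(k, 2))
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- unname((R[pairs[, 1]] - R[pairs[, 2]]) / se)
  p_raw <- 2 * pnorm(-abs(z))
  h <- nrow(pairs)
  if (procedure == "bergmann_hommel") {
    if (k > max_exhaustive_k) {
      abort(paste0(
        "Bergmann-Hommel exhaustive sets are enumerated only for k <= ",
        max_exhaustive_k, "; use procedure = 'holm' for k = ", k
      ))
    }
    sets <- exhaustive_sets(k, pairs)
    p_adj <- vapply(seq_len(h), function(i) {
      vals <- vapply(sets, function(I) {
        if (i %in% I) length(I) * min(p_raw[I]) else NA_real_
      }, numeric(1))
      min(1, max(vals, na.rm = TRUE))
    }, numeric(1))
  } else {
    p_adj <- stats::p.adjust(p_raw, method = "holm")
  }
  p_adj <- pmax(p_adj, p_raw)
  tibble::tibble(
    method_a = methods[pairs[, 1]], method_b = methods[pairs[, 2]],
    z = z, p_raw = p_raw, p_adj = p_adj, procedure = procedure
  )
}

#' Paired t-test wrapper with degenerate-input guard
#'
#' Standard two-sided paired t-test on `a - b` with `n - 1` degrees of
#' freedom; inputs whose differences have zero variance are rejected rather
#' than returning an undefined statistic.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return Tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  check_numeric(a, "a")
  check_numeric(b, "b")
  if (length(a) != length(b) || length(a) < 3) {
    abort("a and b must have equal length >= 3")
  }
  d <- a - b
  if (var(d) == 0) abort("zero variance of paired differences; t undefined")
  ht <- t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Method-comparison evaluation report
#'
#' Joins per-plot predictions from one or more methods to the measured
#' traits and emits accuracy metrics per method x variable x group, plus a
#' pooled row per grouping whenever more than one group is present. With
#' >= 3 methods a Friedman test (blocks = plots, per-plot absolute error)
#' and Bergmann-Hommel post-hoc are run per variable; designated method
#' pairs get a paired t-test on absolute errors.
#'
#' @param predictions Tibble with columns `plot_id`, `method`, and one
#'   column per predicted variable.
#' @param measurements Tibble with `plot_id`, the measured variable columns,
#'   and any grouping columns (`date`, `nitrogen`, ...).
#' @param variables Trait columns to evaluate.
#' @param group Name of the grouping column in `measurements`, or `NULL`
#'   for pooled-only.
#' @param ttest_pairs List of length-2 character vectors of method labels to
#'   compare by paired t-test (default: LUTstd vs LUTreg when both present).
#' @return List of class `evaluation_report`: `metrics` tibble (`method`,
#'   `variable`, `group`, metrics columns), `friedman`, `posthoc`, `ttests`
#'   tibbles.
#' @export
compare_report <- function(predictions, measurements,
                           variables = c("lai", "fcover", "ccc"),
                           group = "date", ttest_pairs = NULL) {
  stopifnot("plot_id" %in% names(predictions),
            "method" %in% names(predictions),
            "plot_id" %in% names(measurements))
  methods <- unique(predictions$method)
  long_pred <- tidyr::pivot_longer(
    predictions[c("plot_id", "method", intersect(variables,
                                                 names(predictions)))],
    cols = -c("plot_id", "method"),
    names_to = "variable", values_to = "predicted"
  )
  meas_cols <- intersect(variables, names(measurements))
  long_obs <- tidyr::pivot_longer(
    measurements[c("plot_id", intersect(group, names(measurements)),
                   meas_cols)],
    cols = dplyr::all_of(meas_cols),
    names_to = "variable", values_to = "observed"
  )
  joined <- dplyr::inner_join(long_pred, long_obs,
                              by = c("plot_id", "variable")) |>
    dplyr::filter(!is.na(.data$predicted), !is.na(.data$observed))
  if (nrow(joined) == 0) abort("predictions and measurements do not join")

  metric_rows <- function(df, label) {
    df |>
      dplyr::group_by(.data$method, .data$variable) |>
      dplyr::filter(dplyr::n() >= 2,
                    max(.data$observed) > min(.data$observed)) |>
      dplyr::summarise(
        retrieval_metrics(.data$observed, .data$predicted),
        .groups = "drop"
      ) |>
      dplyr::mutate(group = label, .after = "variable")
  }

  metrics <- metric_rows(joined, "pooled")
  if (!is.null(group) && group %in% names(joined)) {
    per_group <- joined |>
      dplyr::group_by(grp = .data[[group]]) |>
      dplyr::group_map(~ metric_rows(.x, as.character(.y$grp[1])))
    metrics <- dplyr::bind_rows(dplyr::bind_rows(per_group), metrics)
  }

  friedman <- posthoc <- ttests <- NULL
  err_wide <- joined |>
    dplyr::mutate(abs_err = abs(.data$observed - .data$predicted)) |>
    dplyr::select("plot_id", "method", "variable", "abs_err") |>
    tidyr::pivot_wider(names_from = "method", values_from = "abs_err")
  for (v in unique(err_wide$variable)) {
    m <- err_wide[err_wide$variable == v, methods, drop = FALSE]
    m <- as.matrix(m[stats::complete.cases(m), , drop = FALSE])
    if (length(methods) >= 3 && nrow(m) >= 2) {
      fr <- friedman_rank_test(m)
      fr$variable <- v
      friedman <- dplyr::bind_rows(friedman, fr)
      ph <- pairwise_posthoc(m,
        procedure = if (length(methods) <= 4) "bergmann_hommel" else "holm")
      ph$variable <- v
      posthoc <- dplyr::bind_rows(posthoc, ph)
    }
    if (is.null(ttest_pairs) &&
        all(c("LUTstd", "LUTreg") %in% methods)) {
      ttest_pairs <- list(c("LUTstd", "LUTreg"))
    }
    for (pair in ttest_pairs) {
      if (!all(pair %in% colnames(m)) || nrow(m) < 3) next
      d <- m[, pair[1]] - m[, pair[2]]
      if (var(d) == 0) next
      tt <- paired_ttest(m[, pair[1]], m[, pair[2]])
      tt$variable <- v
      tt$pair <- paste(pair, collapse = " vs ")
      ttests <- dplyr::bind_rows(ttests, tt)
    }
  }
  structure(
    list(metrics = metrics, friedman = friedman, posthoc = posthoc,
         ttests = ttests, methods = methods, group = group),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d method(s): %s\n",
              length(x$methods), toString(x$methods)))
  print(x$metrics, n = 20)
  invisible(x)
}
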