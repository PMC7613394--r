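# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a LUT into one tibble
#'
#' @param x `trait_lut`.
#' @param ... Unused.
#' @return Tibble: trait columns followed by `b<center>` band columns.
#' @method tidy trait_lut
#' @export
tidy.trait_lut <- function(x, ...) {
  bind_spectra(x$traits, x$spectra, x$sensor$center)
}

#' @rdname tidy.trait_lut
#' @method glance trait_lut
#' @export
glance.trait_lut <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = nrow(x$traits),
                 bands = ncol(x$spectra), noise_sigma = x$noise_sigma,
                 seed = x$seed %||% NA_integer_)
}

#' Tidy an empirical line calibration model
#'
#' @param x `elc_model`.
#' @param ... Unused.
#' @return Tibble of per-band gain, offset, fit R^2 and RMSE.
#' @method tidy elc_model
#' @export
tidy.elc_model <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.elc_model
#' @method glance elc_model
#' @export
glance.elc_model <- function(x, ...) {
  tibble::tibble(bands = nrow(x), mean_r2 = mean(x$r2),
                 mean_rmse = mean(x$rmse))
}

#' Tidy an evaluation report
#'
#' @param x `evaluation_report`.
#' @param what `"metrics"`, `"friedman"`, `"posthoc"` or `"ttests"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, what = c("metrics", "friedman",
                                               "posthoc", "ttests"), ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (is.null(out)) {
    return(tibble::tibble())
  }
  tibble::as_tibble(out)
}

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  pooled <- x$metrics[x$metrics$group == "pooled", ]
  tibble::tibble(
    methods = length(x$methods),
    variables = length(unique(x$metrics$variable)),
    groups = length(unique(x$metrics$group)),
    best_method = pooled$method[which.min(pooled$nrmse_pct)],
    best_nrmse_pct = min(pooled$nrmse_pct)
  )
}

#' Tidy a hybrid method/size selection
#'
#' @param x `hybrid_selection`.
#' @param ... Unused.
#' @return The method x size x variable validation score table.
#' @method tidy hybrid_selection
#' @export
tidy.hybrid_selection <- function(x, ...) {
  x$scores
}

#' @rdname tidy.hybrid_selection
#' @method glance hybrid_selection
#' @export
glance.hybrid_selection <- function(x, ...) {
  x$chosen
}

#' Plot per-method accuracy from an evaluation report
#'
#' Bar panel of NRMSE% per method, faceted by variable, for a chosen group
#' (default pooled).
#'
#' @param object `evaluation_report`.
#' @param group Group row to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, group = "pooled", ...) {
  df <- object$metrics[object$metrics$group == group, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$nrmse_pct,
                                   fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "NRMSE (%)",
                  title = paste("Retrieval accuracy,", group)) +
    ggplot2::theme_minimal()
}

#' Plot hybrid learning curves
#'
#' Validation NRMSE% against training-set size per method, faceted by
#' variable; the selected (method, size) is circled.
#'
#' @param object `hybrid_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hybrid_selection
#' @export
autoplot.hybrid_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$size, y = .data$nrmse_pct,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$chosen, shape = 1, size = 4,
                        colour = "black") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "training size", y = "validation NRMSE (%)") +
    ggplot2::theme_minimal()
}

#' Scatter observed vs predicted traits
#'
#' @param estimates `trait_estimates` with `plot_id` and trait columns.
#' @param measurements Tibble with `plot_id` and measured trait columns.
#' @param variable Trait to plot.
#' @return A ggplot object with a 1:1 reference line.
#' @export
plot_retrieval <- function(estimates, measurements, variable = "lai") {
  df <- dplyr::inner_join(
    estimates[c("plot_id", "method", variable)],
    measurements[c("plot_id", variable)],
    by = "plot_id", suffix = c("_pred", "_obs")
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[paste0(variable, "_obs")]],
    y = .data[[paste0(variable, "_pred")]],
    colour = .data$method
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = paste("measured", variable),
                  y = paste("predicted", variable)) +
    ggplot2::theme_minimal()
}
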