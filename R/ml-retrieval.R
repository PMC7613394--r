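# Machine-learning retrieval: hybrid models trained on LUT simulations
# (random forest, Gaussian process regression, canonical correlation
# forest) with training-set-size selection against ground validation, and
# the in-situ random forest with exposure-time covariate under
# leave-one-date-out validation.

#' Specify a regression method for trait retrieval
#'
#' @param method `"rf"` (random forest), `"gpr"` (Gaussian process
#'   regression) or `"ccf"` (canonical correlation forest).
#' @param trees Ensemble size for `rf`/`ccf` (default 500 / 50).
#' @param seed Integer seed making the fit deterministic.
#' @param ... Method-specific settings: `mtry` (rf/ccf), `max_depth`,
#'   `min_node` (ccf), `kernel_var` (gpr nugget).
#' @return List of class `regressor_spec`.
#' @examples
#' regressor_spec("rf", trees = 200)
#' @export
regressor_spec <- function(method = c("rf", "gpr", "ccf"), trees = NULL,
                           seed = 1, ...) {
  method <- match.arg(method)
  trees <- trees %||% switch(method, rf = 500, ccf = 50, gpr = NULL)
  if (!is.null(trees)) check_scalar(trees, "trees", lower = 1)
  structure(list(method = method, trees = trees, seed = seed,
                 opts = list(...)),
            class = "regressor_spec")
}

#' Train a trait regressor on spectra
#'
#' Fits the method named in `spec` to a spectra matrix `X` and trait vector
#' `y`. All methods are deterministic under the spec's seed. The GPR model
#' additionally exposes a predictive standard deviation.
#'
#' @param X Numeric feature matrix (rows = samples, columns = bands or
#'   bands + covariates); >= 10 rows.
#' @param y Numeric trait vector, `length(y) == nrow(X)`.
#' @param spec [regressor_spec()].
#' @return Object of class `trait_regressor`; use [predict.trait_regressor()].
#' @export
train_regressor <- function(X, y, spec = regressor_spec("rf")) {
  X <- as.matrix(X)
  check_numeric(y, "y")
  if (nrow(X) != length(y)) abort("X rows must match length(y)")
  if (nrow(X) < 10) abort("need at least 10 training rows")
  if (anyNA(X) || any(!is.finite(X))) abort("X must be finite")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  constant <- var(y) == 0
  fit <- if (constant) {
    list(value = y[1])
  } else {
    with_seed(spec$seed, switch(spec$method,
      rf = randomForest::randomForest(
        x = X, y = y, ntree = spec$trees,
        mtry = spec$opts$mtry %||% ceiling(ncol(X) / 3)
      ),
      gpr = {
        out <- NULL
        # gausspr prints its sigma-estimation notice via cat(); silence it
        utils::capture.output(
          out <- suppressWarnings(kernlab::gausspr(
            x = X, y = y, variance.model = TRUE,
            var = spec$opts$kernel_var %||% 0.002, kpar = "automatic"
          ))
        )
        out
      },
      ccf = ccf_fit(X, y,
        ntree = spec$trees,
        mtry = spec$opts$mtry %||% max(2L, ceiling(ncol(X) / 3)),
        max_depth = spec$opts$max_depth %||% 8,
        min_node = spec$opts$min_node %||% 5
      )
    ))
  }
  structure(list(spec = spec, fit = fit, constant = constant,
                 features = colnames(X)),
            class = "trait_regressor")
}

#' Predict traits from a fitted regressor
#'
#' @param object [train_regressor()] result.
#' @param newdata Feature matrix with the training columns.
#' @param se Also return the predictive standard deviation (GPR only).
#' @param ... Unused.
#' @return Numeric vector, or a tibble with `fit` and `se` when
#'   `se = TRUE`.
#' @export
predict.trait_regressor <- function(object, newdata, se = FALSE, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$features)) {
    abort(sprintf("newdata has %d columns; the model was trained on %d",
                  ncol(X), length(object$features)))
  }
  colnames(X) <- object$features
  if (object$constant) {
    fit <- rep(object$fit$value, nrow(X))
    if (se) return(tibble::tibble(fit = fit, se = rep(0, nrow(X))))
    return(fit)
  }
  fit <- switch(object$spec$method,
    rf = unname(predict(object$fit, X)),
    gpr = as.numeric(kernlab::predict(object$fit, X)),
    ccf = ccf_predict(object$fit, X)
  )
  if (se) {
    if (object$spec$method != "gpr") {
      abort("predictive standard deviation is available for GPR only")
    }
    s <- as.numeric(kernlab::predict(object$fit, X, type = "sdeviation"))
    return(tibble::tibble(fit = fit, se = s))
  }
  fit
}

# ---- Canonical correlation forest -----------------------------------------
# Ensemble of oblique regression trees. At each node a random subset of
# `mtry` features is projected onto the direction maximally correlated with
# the target (the first canonical coordinate of X_sub vs y, i.e. the
# ridge-stabilized least-squares direction for a scalar target) and the node
# is split at the projection threshold minimizing children's variance.

ccf_fit <- function(X, y, ntree = 50, mtry = max(2L, ceiling(ncol(X) / 3)),
                    max_depth = 8, min_node = 5) {
  n <- nrow(X)
  trees <- lapply(seq_len(ntree), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    ccf_grow(X[idx, , drop = FALSE], y[idx], mtry, max_depth, min_node)
  })
  list(trees = trees, p = ncol(X))
}

ccf_grow <- function(X, y, mtry, depth_left, min_node) {
  n <- length(y)
  if (n < 2 * min_node || depth_left == 0 || var(y) == 0) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  Xs <- X[, feats, drop = FALSE]
  Xc <- sweep(Xs, 2, colMeans(Xs))
  # canonical direction vs scalar y: (X'X + ridge I)^-1 X'y
  g <- crossprod(Xc, y - mean(y))
  G <- crossprod(Xc)
  A <- G + diag(1e-6 * max(1, sum(diag(G))), ncol(Xc))
  w <- tryCatch(solve(A, g), error = function(e) g)
  if (any(!is.finite(w)) || all(w == 0)) w <- g
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm == 0) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  w <- w / nrm # unit direction: projections stay on the feature scale
  proj <- drop(Xs %*% w)
  if (any(!is.finite(proj)) || var(proj) == 0) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  ord <- order(proj)
  ys <- y[ord]
  # best split by minimizing total child SSE via cumulative sums
  cs <- cumsum(ys)
  css <- cumsum(ys^2)
  nl <- seq_len(n - 1)
  sse_l <- css[nl] - cs[nl]^2 / nl
  nr <- n - nl
  sse_r <- (css[n] - css[nl]) - (cs[n] - cs[nl])^2 / nr
  valid <- nl >= min_node & nr >= min_node &
    proj[ord][nl] < proj[ord][pmin(nl + 1, n)]
  if (!any(valid)) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  tot <- sse_l + sse_r
  tot[!valid] <- Inf
  s <- which.min(tot)
  thr <- (proj[ord][s] + proj[ord][s + 1]) / 2
  left <- proj <= thr
  list(
    leaf = FALSE, feats = feats, w = as.numeric(w), thr = thr,
    left = ccf_grow(X[left, , drop = FALSE], y[left], mtry,
                    depth_left - 1, min_node),
    right = ccf_grow(X[!left, , drop = FALSE], y[!left], mtry,
                     depth_left - 1, min_node)
  )
}

ccf_predict_tree <- function(node, X) {
  if (node$leaf) {
    return(rep(node$value, nrow(X)))
  }
  proj <- drop(X[, node$feats, drop = FALSE] %*% node$w)
  out <- numeric(nrow(X))
  left <- proj <= node$thr
  if (any(left)) {
    out[left] <- ccf_predict_tree(node$left, X[left, , drop = FALSE])
  }
  if (any(!left)) {
    out[!left] <- ccf_predict_tree(node$right, X[!left, , drop = FALSE])
  }
  out
}

ccf_predict <- function(fit, X) {
  preds <- vapply(fit$trees, function(tree) ccf_predict_tree(tree, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}

# ---- Hybrid retrieval ------------------------------------------------------

#' Hybrid method and training-size selection against ground validation
#'
#' Draws random subsets of the LUT at each candidate training size, fits
#' each regression method per repeat, scores every fit on the independent
#' ground-validation plots, averages over repeats, and selects the
#' (method, size) with the lowest validation NRMSE per variable (ties go to
#' the smaller size).
#'
#' @param lut [build_lut()] result providing simulated spectra and traits.
#' @param validation Tibble of ground plots: `b<center>` spectral columns
#'   plus measured trait columns named as in `variables`.
#' @param sizes Candidate training sizes (default the 100-5000 ladder).
#' @param repeats Random subsets per size (default 10).
#' @param methods Regressor specs to compare, named list.
#' @param variables Traits to retrieve.
#' @param seed Integer seed driving subset draws and fits.
#' @return List of class `hybrid_selection`: `scores` tibble
#'   (method x size x variable R^2/NRMSE averaged over repeats), `chosen`
#'   tibble, and `models` (the chosen refitted model per variable).
#' @export
hybrid_select <- function(lut, validation,
                          sizes = c(100, 250, 500, 750, 1000, 1500, 2000,
                                    3000, 4000, 5000),
                          repeats = 10,
                          methods = list(rf = regressor_spec("rf"),
                                         gpr = regressor_spec("gpr"),
                                         ccf = regressor_spec("ccf")),
                          variables = c("lai", "fcover", "ccc"),
                          seed = 1) {
  stopifnot(inherits(lut, "trait_lut"))
  if (nrow(validation) == 0) abort("validation set is empty")
  if (max(sizes) > nrow(lut$traits)) {
    abort("largest subset size exceeds the LUT")
  }
  Xv <- spectral_matrix(validation)
  scores <- NULL
  for (s in seq_along(sizes)) {
    sz <- sizes[s]
    for (r in seq_len(repeats)) {
      idx <- with_seed(child_seed(seed, sprintf("subset_%d_%d", sz, r)),
                       sample.int(nrow(lut$traits), sz))
      Xt <- lut$spectra[idx, , drop = FALSE]
      for (mn in names(methods)) {
        for (v in variables) {
          res <- tryCatch({
            spec <- methods[[mn]]
            spec$seed <- child_seed(seed, sprintf("fit_%s_%d_%d_%s",
                                                  mn, sz, r, v))
            model <- train_regressor(Xt, lut$traits[[v]][idx], spec)
            pred <- predict(model, Xv)
            met <- retrieval_metrics(validation[[v]], pred)
            tibble::tibble(method = mn, size = sz, repeat_i = r,
                           variable = v, r2 = met$r2,
                           nrmse_pct = met$nrmse_pct)
          }, error = function(e) {
            warn(sprintf("fit failed (%s, size %d, repeat %d, %s): %s",
                         mn, sz, r, v, conditionMessage(e)))
            NULL
          })
          scores <- dplyr::bind_rows(scores, res)
        }
      }
    }
  }
  summary <- scores |>
    dplyr::group_by(.data$method, .data$size, .data$variable) |>
    dplyr::summarise(r2 = mean(.data$r2, na.rm = TRUE),
                     nrmse_pct = mean(.data$nrmse_pct, na.rm = TRUE),
                     n_repeats = dplyr::n(), .groups = "drop")
  chosen <- summary |>
    dplyr::group_by(.data$variable) |>
    dplyr::arrange(.data$nrmse_pct, .data$size, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  models <- lapply(stats::setNames(chosen$variable, chosen$variable),
    function(v) {
      row <- chosen[chosen$variable == v, ]
      idx <- with_seed(child_seed(seed, sprintf("final_%s", v)),
                       sample.int(nrow(lut$traits), row$size))
      spec <- methods[[row$method]]
      spec$seed <- child_seed(seed, sprintf("finalfit_%s", v))
      train_regressor(lut$spectra[idx, , drop = FALSE],
                      lut$traits[[v]][idx], spec)
    })
  structure(list(scores = summary, raw = scores, chosen = chosen,
                 models = models, sizes = sizes, repeats = repeats),
            class = "hybrid_selection")
}

#' Predict campaign traits with the selected hybrid models
#'
#' @param selection [hybrid_select()] result.
#' @param plots Tibble with `plot_id` and `b<center>` spectral columns.
#' @param method Method label for the output rows.
#' @return `trait_estimates` tibble: `plot_id` plus one column per selected
#'   variable.
#' @export
hybrid_predict <- function(selection, plots, method = "hybrid") {
  X <- spectral_matrix(plots)
  out <- tibble::tibble(plot_id = plots$plot_id)
  for (v in names(selection$models)) {
    out[[v]] <- predict(selection$models[[v]], X)
  }
  out$method <- method
  class(out) <- c("trait_estimates", class(out))
  out
}

# ---- In-situ statistical retrieval ----------------------------------------

#' In-situ random forest retrieval with leave-one-date-out validation
#'
#' For each observation date, trains a random forest on all other dates'
#' plots (features: band reflectances, plus exposure times when
#' `use_exposure = TRUE`) and predicts the held-out date, so every plot is
#' predicted exactly once by a model that never saw its date.
#'
#' @param plots Campaign tibble: `plot_id`, `date`, `b<center>` columns,
#'   measured trait columns, and `exposure_vis`/`exposure_nir` when
#'   `use_exposure`.
#' @param variables Trait columns (measured) to model.
#' @param use_exposure Add exposure-time covariates (the "RFexp" variant).
#' @param spec Random-forest spec.
#' @param measured_suffix Suffix locating the measured trait columns
#'   (`"lai_meas"` etc.); set `""` if the columns are named plainly.
#' @return `trait_estimates` tibble: `plot_id`, `date`, predicted trait
#'   columns, `train_n`, `method` (`"RF"` or `"RFexp"`).
#' @export
insitu_rf_lodo <- function(plots, variables = c("lai", "fcover", "ccc"),
                           use_exposure = FALSE,
                           spec = regressor_spec("rf"),
                           measured_suffix = "_meas") {
  stopifnot("date" %in% names(plots))
  dates <- unique(plots$date)
  if (length(dates) < 2) abort("need >= 2 distinct dates")
  X <- spectral_matrix(plots)
  if (use_exposure) {
    for (cc in c("exposure_vis", "exposure_nir")) {
      if (!cc %in% names(plots)) {
        abort(paste("use_exposure = TRUE needs column", cc))
      }
      X <- cbind(X, plots[[cc]])
      colnames(X)[ncol(X)] <- cc
    }
  }
  cols <- paste0(variables, measured_suffix)
  missing <- setdiff(cols, names(plots))
  if (length(missing)) {
    abort(paste("missing measured trait column(s):", toString(missing)))
  }
  out <- NULL
  for (d in dates) {
    test <- plots$date == d
    if (!any(test)) {
      warn(paste("date", d, "has no plots; skipped"))
      next
    }
    pred <- tibble::tibble(plot_id = plots$plot_id[test],
                           date = plots$date[test],
                           train_n = sum(!test))
    for (j in seq_along(variables)) {
      sp <- spec
      sp$seed <- child_seed(spec$seed, paste0("lodo_", d, "_", variables[j]))
      model <- train_regressor(X[!test, , drop = FALSE],
                               plots[[cols[j]]][!test], sp)
      pred[[variables[j]]] <- predict(model, X[test, , drop = FALSE])
    }
    out <- dplyr::bind_rows(out, pred)
  }
  out$method <- if (use_exposure) "RFexp" else "RF"
  out <- out[match(plots$plot_id, out$plot_id), ]
  class(out) <- c("trait_estimates", class(out))
  out
}
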