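# Shared helpers: spectral column conventions and input validation.
#
# A batch of spectra travels as a wide tibble whose reflectance columns are
# named b<center-wavelength> (e.g. b474, b480.83); everything else is plot
# metadata. These helpers move between that layout and plain matrices.

#' Name spectral columns for a set of band centers
#'
#' @param centers Numeric vector of band center wavelengths (nm).
#' @return Character vector like `"b474"`, `"b480.83"`. Duplicate centers
#'   (overlapping bands of a two-camera sensor) are disambiguated with a
#'   `.1`, `.2`, ... suffix.
#' @export
band_cols <- function(centers) {
  nm <- paste0("b", trimws(formatC(centers, format = "fg", digits = 6)))
  make.unique(nm, sep = "_")
}

#' Extract the spectral matrix from a wide spectra tibble
#'
#' @param df Data frame with `b<wavelength>` reflectance columns.
#' @return Numeric matrix, one row per observation, one column per band.
#' @export
spectral_matrix <- function(df) {
  cols <- grep("^b[0-9]", names(df), value = TRUE)
  if (length(cols) == 0) {
    abort("no spectral columns (named 'b<wavelength>') found")
  }
  as.matrix(df[cols])
}

#' Attach a spectral matrix to a metadata tibble
#' @param meta Tibble of per-observation metadata (may be `NULL`).
#' @param spectra Matrix of reflectances, rows matching `meta`.
#' @param centers Band centers used to name the columns.
#' @return Tibble with metadata columns followed by `b<center>` columns.
#' @export
bind_spectra <- function(meta, spectra, centers) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(centers))
  sp <- tibble::as_tibble(spectra, .name_repair = "minimal")
  names(sp) <- band_cols(centers)
  if (is.null(meta)) {
    return(sp)
  }
  stopifnot(nrow(meta) == nrow(sp))
  dplyr::bind_cols(tibble::as_tibble(meta), sp)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

check_numeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` has values outside [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

# Derive a deterministic child seed from a root seed and a stream label, so
# pipeline stages draw from named substreams of one root seed. Kept < 2^31.
child_seed <- function(seed, stream) {
  ints <- utf8ToInt(stream)
  h <- (sum(ints * seq_along(ints)) * 2654435761) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
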