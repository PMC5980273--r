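#' @keywords internal
"_PACKAGE"

#' Spectral transform kinds
#'
#' The eight re-expressions of leaf reflectance used for band screening:
#' reflectance itself (`"P"`), its reciprocal (`"1/P"`), its base-10
#' logarithm (`"lgP"`), the reciprocal of the logarithm (`"1/lgP"`), and the
#' first-order differential of each of those four (`"P'"`, `"(1/P)'"`,
#' `"(lgP)'"`, `"(1/lgP)'"`).
#'
#' @return A data frame with one row per transform: `kind` (the tag used
#'   throughout the package), `base` (the non-differential transform it is
#'   built from) and `derivative` (logical).
#' @export
#' @examples
#' transform_kinds()
transform_kinds <- function() {
  data.frame(
    kind = c("P", "1/P", "lgP", "1/lgP", "P'", "(1/P)'", "(lgP)'", "(1/lgP)'"),
    base = rep(c("P", "1/P", "lgP", "1/lgP"), 2),
    derivative = rep(c(FALSE, TRUE), each = 4),
    stringsAsFactors = FALSE
  )
}

.check_grid <- function(wavelengths) {
  if (length(wavelengths) < 1L) stop("empty wavelength grid", call. = FALSE)
  if (anyNA(wavelengths)) stop("NA in wavelength grid", call. = FALSE)
  if (length(wavelengths) > 1L) {
    d <- diff(wavelengths)
    if (any(d <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
    if (length(unique(d)) > 1L && diff(range(d)) > 1e-9) {
      stop("non-constant wavelength step", call. = FALSE)
    }
  }
  invisible(wavelengths)
}

#' Single-leaf spectrum
#'
#' A wavelength-indexed vector of reflectance (or a transform of it) for one
#' leaf sample. Wavelengths must be strictly increasing with a constant step
#' (1 nm for ASD-style hyperspectra).
#'
#' @param wavelengths Integer wavelengths in nanometres, strictly increasing,
#'   constant step.
#' @param values Numeric vector, one value per wavelength. For `kind = "P"`
#'   values are unitless reflectance in (0, 1).
#' @param kind Transform tag; one of [transform_kinds()]`$kind`.
#' @return An object of class `"leaf_spectrum"`.
#' @export
#' @examples
#' s <- leaf_spectrum(400:410, runif(11, 0.05, 0.5))
#' grid_step(s)
leaf_spectrum <- function(wavelengths, values, kind = "P") {
  .check_grid(wavelengths)
  kind <- match.arg(kind, transform_kinds()$kind)
  if (length(values) != length(wavelengths)) {
    stop("length(values) != length(wavelengths)", call. = FALSE)
  }
  structure(
    list(wavelengths = as.numeric(wavelengths), values = as.numeric(values),
         kind = kind),
    class = "leaf_spectrum"
  )
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> %s, %d bands (%g-%g nm, step %g nm)\n",
              x$kind, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), grid_step(x)))
  invisible(x)
}

#' Grid step of a spectrum or dataset
#'
#' @param x A `leaf_spectrum` or `spectral_dataset`.
#' @return The constant wavelength step in nm (1 for a single-band grid).
#' @export
grid_step <- function(x) {
  w <- x$wavelengths
  if (length(w) < 2L) return(1)
  w[2L] - w[1L]
}

#' Paired spectra and anthocyanin contents
#'
#' The central container: N leaf spectra on a shared wavelength grid together
#' with the measured leaf anthocyanin content (LAC, mg/g cyanidin 3-glucoside
#' equivalents) of each sample.
#'
#' @param wavelengths Shared wavelength grid (nm), strictly increasing,
#'   constant step.
#' @param values Numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param lac Numeric vector of anthocyanin contents, mg/g, one per sample;
#'   must be non-negative.
#' @param sample_id Character vector of sample identifiers (default
#'   `"S1"..."SN"`).
#' @param kind Transform tag of the stored values (default `"P"`).
#' @return An object of class `"spectral_dataset"`.
#' @export
#' @examples
#' d <- spectral_dataset(500:504, matrix(runif(10, 0.1, 0.4), 2), lac = c(1, 2))
#' n_samples(d); n_bands(d)
spectral_dataset <- function(wavelengths, values, lac,
                             sample_id = NULL, kind = "P") {
  .check_grid(wavelengths)
  kind <- match.arg(kind, transform_kinds()$kind)
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths)) {
    stop("ncol(values) != length(wavelengths)", call. = FALSE)
  }
  if (length(lac) != nrow(values)) {
    stop("length(lac) != number of samples", call. = FALSE)
  }
  if (any(lac < 0, na.rm = TRUE)) stop("lac values must be >= 0", call. = FALSE)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  dimnames(values) <- list(sample_id, paste0("w", wavelengths))
  structure(
    list(wavelengths = as.numeric(wavelengths), values = values,
         lac = as.numeric(lac), sample_id = as.character(sample_id),
         kind = kind),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d bands (%g-%g nm), kind %s\n",
    n_samples(x), n_bands(x), min(x$wavelengths), max(x$wavelengths), x$kind))
  cat(sprintf("  LAC: %.3g-%.3g mg/g (mean %.3g)\n",
              min(x$lac), max(x$lac), mean(x$lac)))
  invisible(x)
}

#' @rdname spectral_dataset
#' @param x A `spectral_dataset`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname spectral_dataset
#' @export
n_bands <- function(x) length(x$wavelengths)

#' Subset a dataset by sample id or index
#'
#' @param dataset A `spectral_dataset`.
#' @param ids Character sample ids or integer row indices.
#' @return A `spectral_dataset` with the selected samples, in the given order.
#' @export
subset_samples <- function(dataset, ids) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.character(ids)) {
    idx <- match(ids, dataset$sample_id)
    if (anyNA(idx)) {
      stop("unknown sample ids: ", paste(ids[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(ids)
    if (any(idx < 1L | idx > n_samples(dataset))) {
      stop("sample index out of range", call. = FALSE)
    }
  }
  spectral_dataset(dataset$wavelengths,
                   dataset$values[idx, , drop = FALSE],
                   dataset$lac[idx],
                   dataset$sample_id[idx],
                   dataset$kind)
}

#' Average replicate scans of one leaf
#'
#' Field protocol scans each leaf several times (ten in the reference
#' protocol) and uses the pointwise arithmetic mean as the leaf's spectrum.
#'
#' @param spectra A list of `leaf_spectrum` objects with identical grids,
#'   all of kind `"P"`.
#' @return A single `leaf_spectrum`, the pointwise mean.
#' @export
#' @examples
#' reps <- replicate(10, leaf_spectrum(400:405, runif(6, 0.1, 0.3)),
#'                   simplify = FALSE)
#' average_replicates(reps)
average_replicates <- function(spectra) {
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  if (!all(vapply(spectra, inherits, logical(1), "leaf_spectrum"))) {
    stop("all elements must be leaf_spectrum objects", call. = FALSE)
  }
  w <- spectra[[1L]]$wavelengths
  for (s in spectra) {
    if (s$kind != "P") stop("replicates must be raw reflectance (kind P)",
                            call. = FALSE)
    if (!identical(length(s$wavelengths), length(w)) ||
        any(s$wavelengths != w)) {
      stop("mismatched wavelength grids among replicates", call. = FALSE)
    }
  }
  m <- vapply(spectra, `[[`, numeric(length(w)), "values")
  leaf_spectrum(w, rowMeans(as.matrix(m)), kind = "P")
}

#' Restrict a dataset to a wavelength window
#'
#' Screening is performed on 400--1400 nm by default: beyond 1400 nm leaf
#' reflectance is dominated by the 1450/1940 nm water absorptions and
#' instrument noise, so those bands are excluded before correlation analysis.
#'
#' @param dataset A `spectral_dataset`.
#' @param lo_nm,hi_nm Inclusive window bounds in nm (defaults 400 and 1400).
#' @return The dataset restricted to grid points inside `[lo_nm, hi_nm]`.
#' @export
restrict_range <- function(dataset, lo_nm = 400, hi_nm = 1400) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (lo_nm >= hi_nm) stop("lo_nm must be < hi_nm", call. = FALSE)
  keep <- dataset$wavelengths >= lo_nm & dataset$wavelengths <= hi_nm
  if (!any(keep)) {
    stop(sprintf("range [%g, %g] does not intersect the grid", lo_nm, hi_nm),
         call. = FALSE)
  }
  spectral_dataset(dataset$wavelengths[keep],
                   dataset$values[, keep, drop = FALSE],
                   dataset$lac, dataset$sample_id, dataset$kind)
}
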