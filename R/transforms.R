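# Elementwise base transforms. P is validated to lie strictly inside (0, 1)
# so lgP < 0 and 1/lgP is finite; callers choose what happens to violations.
.base_transform <- function(values, base, mode = c("strict", "mask")) {
  mode <- match.arg(mode)
  if (base == "P") return(values)
  bad <- !is.na(values) & (values <= 0 | values >= 1)
  if (any(bad)) {
    if (mode == "strict") {
      ij <- which(bad, arr.ind = is.matrix(values))
      stop(sprintf("%s singular: reflectance outside (0,1) at %d point(s)",
                   base, sum(bad)), call. = FALSE)
    }
    values[bad] <- NA_real_
  }
  switch(base,
         "1/P"   = 1 / values,
         "lgP"   = log10(values),
         "1/lgP" = 1 / log10(values),
         stop("unknown base transform ", base, call. = FALSE))
}

#' First-order spectral differential
#'
#' The printed (default) form divides the backward difference by twice the
#' grid step: at wavelength \eqn{\lambda_i} the differential is
#' \eqn{[v(\lambda_i) - v(\lambda_{i-1})] / (2\Delta\lambda)}, attached to
#' the right endpoint \eqn{\lambda_i}, so the output grid drops the first
#' band. This is half the usual backward difference; correlation screening
#' and determination coefficients are invariant to that constant factor.
#' `mode = "central"` instead uses
#' \eqn{[v(\lambda_{i+1}) - v(\lambda_{i-1})] / (2\Delta\lambda)} and drops
#' both end bands.
#'
#' @param x A `leaf_spectrum` or `spectral_dataset`.
#' @param mode `"printed"` (half backward difference, default) or
#'   `"central"`.
#' @param delta_lambda Grid step Δλ in nm; defaults to the step of `x`'s
#'   grid, and must equal it.
#' @return An object of the same class on the reduced grid, with the
#'   derivative transform tag.
#' @export
#' @examples
#' s <- leaf_spectrum(400:410, (400:410) / 1000)
#' first_derivative(s)$values  # constant 0.0005
first_derivative <- function(x, mode = c("printed", "central"),
                             delta_lambda = NULL) {
  mode <- match.arg(mode)
  UseMethod("first_derivative")
}

.deriv_values <- function(v, step, mode) {
  # v: matrix samples x bands (or 1 x bands)
  p <- ncol(v)
  if (mode == "printed") {
    (v[, -1L, drop = FALSE] - v[, -p, drop = FALSE]) / (2 * step)
  } else {
    (v[, -c(1L, 2L), drop = FALSE] - v[, -c(p - 1L, p), drop = FALSE]) /
      (2 * step)
  }
}

.deriv_kind <- function(kind) {
  tk <- transform_kinds()
  if (tk$derivative[match(kind, tk$kind)]) {
    stop("spectrum is already a differential (", kind, ")", call. = FALSE)
  }
  tk$kind[tk$base == kind & tk$derivative]
}

#' @export
first_derivative.leaf_spectrum <- function(x, mode = c("printed", "central"),
                                           delta_lambda = NULL) {
  mode <- match.arg(mode)
  need <- if (mode == "printed") 2L else 3L
  if (length(x$wavelengths) < need) {
    stop("need at least ", need, " grid points", call. = FALSE)
  }
  step <- grid_step(x)
  if (!is.null(delta_lambda) && abs(delta_lambda - step) > 1e-9) {
    stop("delta_lambda must equal the grid step (", step, " nm)",
         call. = FALSE)
  }
  v <- .deriv_values(matrix(x$values, nrow = 1L), step, mode)
  w <- if (mode == "printed") x$wavelengths[-1L] else
    x$wavelengths[-c(1L, length(x$wavelengths))]
  leaf_spectrum(w, drop(v), kind = .deriv_kind(x$kind))
}

#' @export
first_derivative.spectral_dataset <- function(x,
                                              mode = c("printed", "central"),
                                              delta_lambda = NULL) {
  mode <- match.arg(mode)
  need <- if (mode == "printed") 2L else 3L
  if (n_bands(x) < need) stop("need at least ", need, " grid points",
                              call. = FALSE)
  step <- grid_step(x)
  if (!is.null(delta_lambda) && abs(delta_lambda - step) > 1e-9) {
    stop("delta_lambda must equal the grid step (", step, " nm)",
         call. = FALSE)
  }
  v <- .deriv_values(x$values, step, mode)
  w <- if (mode == "printed") x$wavelengths[-1L] else
    x$wavelengths[-c(1L, n_bands(x))]
  spectral_dataset(w, v, x$lac, x$sample_id, kind = .deriv_kind(x$kind))
}

#' Apply one of the eight spectral transforms
#'
#' Re-expresses raw reflectance P as one of P, 1/P, lg P (base-10 logarithm),
#' 1/lg P, or the first-order differential of any of those. Differential
#' kinds compose [first_derivative()] after the base transform, so their
#' output grid drops the first band (`"printed"` mode) or both end bands
#' (`"central"` mode).
#'
#' @param dataset A `spectral_dataset` of kind `"P"`.
#' @param kind Target transform tag, one of [transform_kinds()]`$kind`.
#' @param derivative_mode Differencing scheme for differential kinds; see
#'   [first_derivative()].
#' @param on_singular What to do when a reflectance value lies outside
#'   (0, 1), where the log-based transforms are undefined: `"strict"`
#'   (default) raises an error; `"mask"` marks the value `NA` so the affected
#'   band is excluded from screening for this transform only.
#' @return A `spectral_dataset` carrying the transformed values.
#' @export
#' @examples
#' d <- spectral_dataset(500:504, matrix(0.1, 2, 5), lac = c(1, 2))
#' apply_transform(d, "1/lgP")$values[1, 1]  # 1/log10(0.1) = -1
apply_transform <- function(dataset, kind,
                            derivative_mode = c("printed", "central"),
                            on_singular = c("strict", "mask")) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  tk <- transform_kinds()
  kind <- match.arg(kind, tk$kind)
  derivative_mode <- match.arg(derivative_mode)
  on_singular <- match.arg(on_singular)
  if (dataset$kind != "P") {
    stop("apply_transform expects raw reflectance (kind P), got ",
         dataset$kind, call. = FALSE)
  }
  row <- tk[tk$kind == kind, ]
  v <- .base_transform(dataset$values, row$base, on_singular)
  out <- spectral_dataset(dataset$wavelengths, v, dataset$lac,
                          dataset$sample_id, kind = row$base)
  if (row$derivative) out <- first_derivative(out, mode = derivative_mode)
  out
}
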