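#' Per-wavelength correlation spectrum
#'
#' For each band i, the Pearson correlation between the (possibly
#' transformed) band values across samples and the anthocyanin content:
#' \deqn{r_i = \frac{\sum_n (P_{ni} - \bar P_i)(LAC_n - \overline{LAC})}
#'   {\sqrt{\sum_n (P_{ni} - \bar P_i)^2 \sum_n (LAC_n - \overline{LAC})^2}}}
#' Bands where the transform is undefined for any sample (masked values) or
#' where the band has zero variance are marked `NA`, never 0 — they are
#' excluded from band selection, not counted as uncorrelated.
#'
#' @param dataset A [spectral_dataset()] (any transform kind), N >= 3
#'   samples, non-constant LAC.
#' @return An object of class `"correlation_spectrum"`: a list with
#'   `wavelengths`, `r`, `transform` (the dataset's kind) and `n`.
#' @export
#' @examples
#' d <- spectral_dataset(500:502, cbind(1:4 * 2 + 5, rnorm(4), 4:1),
#'                       lac = 1:4)
#' correlation_spectrum(d)$r[1]  # exactly 1: band is affine in LAC
correlation_spectrum <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- n_samples(dataset)
  if (n < 3L) stop("need at least 3 samples to screen", call. = FALSE)
  y <- dataset$lac
  if (max(y) - min(y) <= 0) stop("trait has zero variance", call. = FALSE)
  v <- dataset$values
  yc <- y - mean(y)
  syy <- sum(yc^2)
  usable <- colSums(is.na(v)) == 0L
  r <- rep(NA_real_, ncol(v))
  if (any(usable)) {
    vu <- v[, usable, drop = FALSE]
    vc <- sweep(vu, 2L, colMeans(vu))
    sxx <- colSums(vc^2)
    sxy <- as.vector(crossprod(vc, yc))
    ru <- ifelse(sxx > 0, sxy / sqrt(sxx * syy), NA_real_)
    r[usable] <- ru
  }
  structure(
    list(wavelengths = dataset$wavelengths, r = r,
         transform = dataset$kind, n = n),
    class = "correlation_spectrum"
  )
}

#' @export
print.correlation_spectrum <- function(x, ...) {
  cat(sprintf("<correlation_spectrum> %s, %d bands, n = %d, max |r| = %.3f\n",
              x$transform, length(x$wavelengths), x$n,
              max(abs(x$r), na.rm = TRUE)))
  invisible(x)
}

#' Select the sensitive band
#'
#' The sensitive band of a transform is the wavelength with maximal absolute
#' Pearson correlation to the trait. Ties are broken by the smallest
#' wavelength; `NA` (masked) bands are ignored.
#'
#' @param cs A [correlation_spectrum()].
#' @return A list of class `"sensitive_band"` with `wavelength` (nm), `r`
#'   (signed correlation at that band) and `transform`.
#' @export
select_sensitive_band <- function(cs) {
  stopifnot(inherits(cs, "correlation_spectrum"))
  ok <- which(!is.na(cs$r))
  if (!length(ok)) stop("all bands masked: nothing to select", call. = FALSE)
  best <- ok[which.max(abs(cs$r[ok]))]  # which.max: first (lowest-nm) winner
  structure(
    list(wavelength = cs$wavelengths[best], r = cs$r[best],
         transform = cs$transform),
    class = "sensitive_band"
  )
}

#' @export
print.sensitive_band <- function(x, ...) {
  cat(sprintf("<sensitive_band> %s: %g nm, r = %.3f\n",
              x$transform, x$wavelength, x$r))
  invisible(x)
}

#' Screen all eight transforms for sensitive bands
#'
#' Applies each spectral transform to the (range-restricted) reflectance
#' dataset, computes its correlation spectrum against anthocyanin content,
#' and selects the sensitive band of each.
#'
#' @param dataset A reflectance [spectral_dataset()] (kind `"P"`), already
#'   restricted to the screening range (see [restrict_range()]).
#' @param kinds Transform tags to screen (default: all eight).
#' @param derivative_mode Differencing scheme passed to [apply_transform()].
#' @param on_singular Passed to [apply_transform()]; default `"mask"` so a
#'   stray out-of-domain value disables only the affected bands of the
#'   log-based transforms.
#' @return A list of class `"screening_result"`, one element per transform,
#'   each with `transform`, `band` (a `sensitive_band`), `cs` (the full
#'   `correlation_spectrum`) and `n_bands_screened`.
#' @export
screen_all_transforms <- function(dataset, kinds = transform_kinds()$kind,
                                  derivative_mode = c("printed", "central"),
                                  on_singular = c("mask", "strict")) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  derivative_mode <- match.arg(derivative_mode)
  on_singular <- match.arg(on_singular)
  kinds <- match.arg(kinds, transform_kinds()$kind, several.ok = TRUE)
  out <- lapply(kinds, function(k) {
    tds <- apply_transform(dataset, k, derivative_mode = derivative_mode,
                           on_singular = on_singular)
    cs <- correlation_spectrum(tds)
    list(transform = k, band = select_sensitive_band(cs), cs = cs,
         n_bands_screened = sum(!is.na(cs$r)))
  })
  names(out) <- kinds
  class(out) <- "screening_result"
  out
}

#' @export
print.screening_result <- function(x, ...) {
  print(screening_report(x))
  invisible(x)
}

#' Tabulate a screening result
#'
#' @param screen A `screening_result` from [screen_all_transforms()].
#' @return A data frame with one row per transform: `transform`,
#'   `sensitive_band_nm`, `r`, `n_bands_screened`, `n_samples`.
#' @export
screening_report <- function(screen) {
  stopifnot(inherits(screen, "screening_result"))
  do.call(rbind, lapply(screen, function(e) {
    data.frame(transform = e$transform,
               sensitive_band_nm = e$band$wavelength,
               r = e$band$r,
               n_bands_screened = e$n_bands_screened,
               n_samples = e$cs$n,
               stringsAsFactors = FALSE)
  }))
}

#' Export correlation spectra in long format
#'
#' @param screen A `screening_result`.
#' @return A data frame `(transform, wavelength_nm, r)` suitable for
#'   plotting correlation curves per transform.
#' @export
correlation_long <- function(screen) {
  stopifnot(inherits(screen, "screening_result"))
  do.call(rbind, lapply(screen, function(e) {
    data.frame(transform = e$transform,
               wavelength_nm = e$cs$wavelengths,
               r = e$cs$r, stringsAsFactors = FALSE)
  }))
}
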