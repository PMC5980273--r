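#' Calibration model families
#'
#' The five single-predictor families used to calibrate anthocyanin content
#' against the sensitive-band value X: linear (Y = aX + b), quadratic
#' polynomial (Y = aX^2 + bX + c), power (Y = aX^b), exponential
#' (Y = a e^(bX)) and logarithmic (Y = a ln(X) + b).
#'
#' @return Character vector of the five family names.
#' @export
model_families <- function() {
  c("linear", "poly2", "power", "exponential", "logarithmic")
}

.family_ncoef <- function(family) {
  switch(family, linear = 2L, poly2 = 3L, power = 2L, exponential = 2L,
         logarithmic = 2L)
}

.r2 <- function(y, yhat) {
  ok <- !is.na(yhat)
  ss_tot <- sum((y[ok] - mean(y[ok]))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum((y[ok] - yhat[ok])^2) / ss_tot
}

.skipped <- function(family, reason, n_fit = 0L) {
  structure(
    list(family = family, coefficients = NULL, r2 = NA_real_,
         r2_log = NA_real_, n_fit = n_fit, n_excluded = NA_integer_,
         status = "skipped", reason = reason,
         transform = NA_character_, band = NA_real_),
    class = "calibration_fit"
  )
}

#' Fit one calibration family
#'
#' Fits anthocyanin content `y` (mg/g) against sensitive-band values `x` by
#' least squares. Linear, quadratic and logarithmic families are solved in
#' closed form (ordinary least squares); power and exponential families are
#' refined by Levenberg--Marquardt nonlinear least squares on the original
#' scale, started from the log-linearised closed form, so the reported R^2
#' (`1 - SS_res/SS_tot`, original scale) is comparable across families. For
#' power and exponential fits the log-space R^2 of the linearised regression
#' (the spreadsheet-trendline convention) is also reported as `r2_log`.
#'
#' Points violating a family's domain (x <= 0 for power and logarithmic) are
#' excluded; if more than `max_excluded_frac` of the points are excluded, or
#' too few points remain, the family is marked skipped rather than raising
#' an error — some differential transforms are wholly or largely negative,
#' so power/logarithmic fits are simply unavailable for them.
#'
#' @param x Numeric predictor (transformed reflectance at one band).
#' @param y Numeric response, anthocyanin content mg/g.
#' @param family One of [model_families()].
#' @param max_excluded_frac Maximum tolerated fraction of domain-excluded
#'   points before the family is skipped (default 0.1).
#' @return An object of class `"calibration_fit"`: `family`, named
#'   `coefficients` (a, b and for poly2 c), `r2`, `r2_log`, `n_fit`,
#'   `n_excluded`, `status` (`"ok"` or `"skipped"`) and `reason`.
#' @export
#' @examples
#' f <- fit_model(1:10, 2 * (1:10) + 1, "linear")
#' coef(f)  # a = 2, b = 1
fit_model <- function(x, y, family = model_families(),
                      max_excluded_frac = 0.1) {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("length(x) != length(y)", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n0 <- length(x)
  ncoef <- .family_ncoef(family)

  dom <- if (family %in% c("power", "logarithmic")) x > 0 else rep(TRUE, n0)
  n_excluded <- sum(!dom)
  if (n0 == 0L || n_excluded / max(n0, 1L) > max_excluded_frac) {
    return(.skipped(family, sprintf(
      "%d/%d points outside domain (x <= 0)", n_excluded, n0)))
  }
  x <- x[dom]; y <- y[dom]
  n <- length(x)
  if (n < ncoef + 1L) {
    return(.skipped(family, sprintf("n = %d < %d required", n, ncoef + 1L), n))
  }

  fit <- switch(
    family,
    linear = {
      cf <- stats::coef(stats::lm(y ~ x))
      list(coefficients = c(a = unname(cf[2L]), b = unname(cf[1L])),
           pred = cf[1L] + cf[2L] * x, r2_log = NA_real_)
    },
    poly2 = {
      cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
      list(coefficients = c(a = unname(cf[3L]), b = unname(cf[2L]),
                            c = unname(cf[1L])),
           pred = cf[1L] + cf[2L] * x + cf[3L] * x^2, r2_log = NA_real_)
    },
    logarithmic = {
      lx <- log(x)
      cf <- stats::coef(stats::lm(y ~ lx))
      list(coefficients = c(a = unname(cf[2L]), b = unname(cf[1L])),
           pred = cf[1L] + cf[2L] * lx, r2_log = NA_real_)
    },
    power = .fit_loglinearised(x, y, log_x = TRUE),
    exponential = .fit_loglinearised(x, y, log_x = FALSE)
  )
  if (!is.null(fit$skipped)) return(.skipped(family, fit$skipped, n))

  structure(
    list(family = family, coefficients = fit$coefficients,
         r2 = .r2(y, fit$pred), r2_log = fit$r2_log,
         n_fit = n, n_excluded = n_excluded,
         status = "ok", reason = NA_character_,
         transform = NA_character_, band = NA_real_),
    class = "calibration_fit"
  )
}

# Power (log_x = TRUE): y = a * x^b; exponential: y = a * exp(b * x).
# Both are linear in log y, giving the start values; the final fit minimises
# squared error on the original y scale. Internally parameterised as
# log(a) + b*(log x | x) because Table-1-scale coefficients span many orders
# of magnitude (a up to ~1e9).
.fit_loglinearised <- function(x, y, log_x) {
  pos <- y > 0
  if (sum(pos) < 3L) {
    return(list(skipped = "too few y > 0 points for log-space start"))
  }
  z <- if (log_x) log(x) else x
  lmfit <- stats::lm(log(y[pos]) ~ z[pos])
  init <- stats::coef(lmfit)
  r2_log <- .r2(log(y[pos]), stats::fitted(lmfit))
  start <- list(loga = unname(init[1L]), b = unname(init[2L]))
  ss <- function(loga, b) sum((y - exp(loga + b * z))^2)
  ss_init <- ss(start$loga, start$b)
  cf <- tryCatch({
    nl <- minpack.lm::nlsLM(y ~ exp(loga + b * z),
                            start = start,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
    stats::coef(nl)
  }, error = function(e) unlist(start))
  # never accept a refinement that is worse than its start
  if (ss(cf[["loga"]], cf[["b"]]) > ss_init) cf <- unlist(start)
  a <- exp(cf[["loga"]]); b <- cf[["b"]]
  pred <- if (log_x) a * x^b else a * exp(b * x)
  list(coefficients = c(a = a, b = b), pred = pred, r2_log = r2_log)
}

#' @export
coef.calibration_fit <- function(object, ...) object$coefficients

#' Evaluate a fitted calibration model
#'
#' @param object A `"calibration_fit"`.
#' @param newdata Numeric vector of predictor values (band values).
#' @param on_domain `"error"` (default) stops on values outside the family's
#'   domain (x <= 0 for power/logarithmic); `"na"` returns `NA` for them.
#' @param ... Unused.
#' @return Predicted anthocyanin content, mg/g.
#' @export
predict.calibration_fit <- function(object, newdata,
                                    on_domain = c("error", "na"), ...) {
  on_domain <- match.arg(on_domain)
  if (object$status != "ok") stop("cannot predict from a skipped fit",
                                  call. = FALSE)
  x <- as.numeric(newdata)
  cf <- object$coefficients
  bad <- if (object$family %in% c("power", "logarithmic")) x <= 0
         else rep(FALSE, length(x))
  bad <- bad | is.na(x)
  if (any(bad) && on_domain == "error" && any(bad & !is.na(x))) {
    stop(object$family, " model undefined for x <= 0", call. = FALSE)
  }
  xs <- ifelse(bad, NA_real_, x)
  out <- switch(object$family,
                linear = cf[["a"]] * xs + cf[["b"]],
                poly2 = cf[["a"]] * xs^2 + cf[["b"]] * xs + cf[["c"]],
                power = cf[["a"]] * xs^cf[["b"]],
                exponential = cf[["a"]] * exp(cf[["b"]] * xs),
                logarithmic = cf[["a"]] * log(xs) + cf[["b"]])
  unname(out)
}

#' Render a fitted model as a Table-style equation
#'
#' @param fit A `"calibration_fit"` (with `band` set when fitted through
#'   [fit_all_candidates()]).
#' @param digits Significant digits for coefficients (default 4).
#' @return A single equation string, e.g. `"y = 21.26*W685 - 0.0267"`.
#' @export
equation_string <- function(fit, digits = 4) {
  if (fit$status != "ok") return(sprintf("skipped (%s)", fit$reason))
  cf <- lapply(fit$coefficients, signif, digits = digits)
  W <- if (is.na(fit$band)) "x" else sprintf("W%g", fit$band)
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  addterm <- function(v) if (v >= 0) paste0(" + ", fmt(v))
                         else paste0(" - ", fmt(abs(v)))
  switch(fit$family,
         linear = sprintf("y = %s*%s%s", fmt(cf$a), W, addterm(cf$b)),
         poly2 = sprintf("y = %s*%s^2%s*%s%s", fmt(cf$a), W,
                         addterm(cf$b), W, addterm(cf$c)),
         power = sprintf("y = %s*%s^%s", fmt(cf$a), W, fmt(cf$b)),
         exponential = sprintf("y = %s*exp(%s*%s)", fmt(cf$a), fmt(cf$b), W),
         logarithmic = sprintf("y = %s*ln(%s)%s", fmt(cf$a), W,
                               addterm(cf$b)))
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<calibration_fit> %s%s: %s  (R2 = %.3f, n = %d)\n",
                x$family,
                if (is.na(x$transform)) "" else paste0(" [", x$transform, "]"),
                equation_string(x), x$r2, x$n_fit))
  } else {
    cat(sprintf("<calibration_fit> %s: skipped (%s)\n", x$family, x$reason))
  }
  invisible(x)
}

#' Fit every family at every transform's sensitive band
#'
#' For each screened transform, extracts the sensitive-band values from the
#' transformed training data and fits all five families, producing the
#' candidate grid from which the final calibration is chosen.
#'
#' @param dataset Training reflectance [spectral_dataset()] (kind `"P"`),
#'   restricted to the screening range.
#' @param screen A `screening_result` from [screen_all_transforms()] on the
#'   same (or equally-gridded) training data.
#' @param families Families to try (default all five).
#' @param derivative_mode Passed to [apply_transform()].
#' @param max_excluded_frac Passed to [fit_model()].
#' @return A list of class `"candidate_set"` of `"calibration_fit"` objects,
#'   each annotated with its `transform` and `band`.
#' @export
fit_all_candidates <- function(dataset, screen,
                               families = model_families(),
                               derivative_mode = c("printed", "central"),
                               max_excluded_frac = 0.1) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(screen, "screening_result"))
  derivative_mode <- match.arg(derivative_mode)
  families <- match.arg(families, model_families(), several.ok = TRUE)
  out <- list()
  for (entry in screen) {
    tds <- apply_transform(dataset, entry$transform,
                           derivative_mode = derivative_mode,
                           on_singular = "mask")
    j <- match(entry$band$wavelength, tds$wavelengths)
    if (is.na(j)) {
      stop("sensitive band ", entry$band$wavelength,
           " nm not on the transformed grid", call. = FALSE)
    }
    xb <- tds$values[, j]
    for (fam in families) {
      fit <- fit_model(xb, tds$lac, fam, max_excluded_frac)
      fit$transform <- entry$transform
      fit$band <- entry$band$wavelength
      out[[length(out) + 1L]] <- fit
    }
  }
  class(out) <- "candidate_set"
  out
}

#' Tabulate a candidate set
#'
#' @param candidates A `"candidate_set"`.
#' @return Data frame with columns transform, band_nm, family, a, b, c,
#'   r2_original_scale, r2_log_scale, n_fit, status, reason, equation.
#' @export
candidate_grid <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  do.call(rbind, lapply(candidates, function(f) {
    cf <- f$coefficients
    data.frame(transform = f$transform, band_nm = f$band, family = f$family,
               a = if (is.null(cf)) NA_real_ else cf[["a"]],
               b = if (is.null(cf)) NA_real_ else cf[["b"]],
               c = if (!is.null(cf) && "c" %in% names(cf)) cf[["c"]]
                   else NA_real_,
               r2_original_scale = f$r2, r2_log_scale = f$r2_log,
               n_fit = f$n_fit, status = f$status, reason = f$reason,
               equation = equation_string(f),
               stringsAsFactors = FALSE)
  }))
}

#' Select the best calibration model
#'
#' Picks the candidate with maximal original-scale R^2 among non-skipped
#' fits. Ties are broken by fewer coefficients (simpler family), then by
#' lower band wavelength.
#'
#' @param candidates A `"candidate_set"` (or plain list of
#'   `"calibration_fit"` objects).
#' @return The winning `"calibration_fit"`.
#' @export
select_best_model <- function(candidates) {
  ok <- Filter(function(f) f$status == "ok", candidates)
  if (!length(ok)) stop("all candidate fits were skipped", call. = FALSE)
  r2 <- vapply(ok, `[[`, numeric(1), "r2")
  ncoef <- vapply(ok, function(f) .family_ncoef(f$family), integer(1))
  band <- vapply(ok, function(f) ifelse(is.na(f$band), Inf, f$band),
                 numeric(1))
  ord <- order(-r2, ncoef, band)
  ok[[ord[1L]]]
}
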