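#' Random train/validation split
#'
#' Draws a uniform random split without replacement, reproducible from
#' `seed` (the RNG state of the session is left untouched). The reference
#' design uses 400 training and 100 validation samples out of 500; for other
#' dataset sizes pass sizes explicitly or keep the default 80/20 proportion.
#' `stratify = TRUE` balances the split across LAC quartiles.
#'
#' @param dataset A [spectral_dataset()].
#' @param n_train,n_test Split sizes; `n_train + n_test` must not exceed N.
#'   Defaults: 80% / 20% of N (400/100 at N = 500).
#' @param seed Integer seed making the split reproducible.
#' @param stratify Balance the draw across LAC quartiles (default FALSE).
#' @return A list of class `"split_plan"` with `train_ids`, `test_ids`
#'   (disjoint character vectors) and `seed`.
#' @export
split_train_test <- function(dataset, n_train = NULL, n_test = NULL,
                             seed = 1L, stratify = FALSE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- n_samples(dataset)
  if (is.null(n_train)) n_train <- round(0.8 * n)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test > n) {
    stop(sprintf("n_train + n_test = %d exceeds N = %d", n_train + n_test, n),
         call. = FALSE)
  }
  if (n_train < 1L || n_test < 1L) stop("both split sizes must be >= 1",
                                        call. = FALSE)
  ids <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      q <- cut(rank(dataset$lac, ties.method = "first"),
               breaks = 4L, labels = FALSE)
      picked <- unlist(lapply(split(seq_len(n), q), function(ix) {
        k <- round(length(ix) * n_train / n)
        sample(ix, min(k, length(ix)))
      }), use.names = FALSE)
      # adjust to the exact requested size
      if (length(picked) > n_train) picked <- sample(picked, n_train)
      if (length(picked) < n_train) {
        picked <- c(picked, sample(setdiff(seq_len(n), picked),
                                   n_train - length(picked)))
      }
      rest <- setdiff(seq_len(n), picked)
      list(train = sort(picked), test = sort(sample(rest, n_test)))
    } else {
      picked <- sample(seq_len(n), n_train + n_test)
      list(train = sort(picked[seq_len(n_train)]),
           test = sort(picked[n_train + seq_len(n_test)]))
    }
  })
  structure(list(train_ids = dataset$sample_id[ids$train],
                 test_ids = dataset$sample_id[ids$test],
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Root mean square error
#'
#' \deqn{RMSE = \sqrt{\sum_i (LAC_i - PLAC_i)^2 / N}}
#' between measured and predicted anthocyanin content (mg/g).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param na.rm Drop pairs with missing predictions (default FALSE).
#' @return RMSE, in the units of the inputs.
#' @export
#' @examples
#' rmse(c(0, 2), c(1, 1))  # 1
rmse <- function(observed, predicted, na.rm = FALSE) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  if (!length(observed)) stop("need at least one pair", call. = FALSE)
  d <- observed - predicted
  if (na.rm) d <- d[!is.na(d)]
  sqrt(sum(d^2) / length(d))
}

#' Evaluate a calibration model on a dataset
#'
#' Applies the model's spectral transform to the dataset, extracts the
#' model's band, predicts anthocyanin content and compares against the
#' measured values. Two determination coefficients are reported:
#' `r2` = 1 - SS_res/SS_tot on the original scale (can be negative on
#' held-out data) and `r2_cor`, the squared Pearson correlation between
#' observed and predicted (the scatter-plot convention). Samples whose band
#' value falls outside the model family's domain get `NA` predictions; they
#' are counted in `n_domain_violations` and dropped from the statistics.
#'
#' @param model A `"calibration_fit"` with `transform` and `band` set.
#' @param dataset A reflectance [spectral_dataset()] (kind `"P"`) covering
#'   the model's band.
#' @param derivative_mode Passed to [apply_transform()]; must match the mode
#'   used in fitting.
#' @param stratum Optional label describing the evaluated subset.
#' @return A list of class `"validation_report"`: `r2`, `r2_cor`, `rmse`
#'   (mg/g), `n`, `n_domain_violations`, `stratum`, plus the model's
#'   transform/band/family.
#' @export
evaluate_model <- function(model, dataset,
                           derivative_mode = c("printed", "central"),
                           stratum = NA_character_) {
  stopifnot(inherits(model, "calibration_fit"),
            inherits(dataset, "spectral_dataset"))
  derivative_mode <- match.arg(derivative_mode)
  if (model$status != "ok") stop("cannot evaluate a skipped fit",
                                 call. = FALSE)
  if (is.na(model$transform) || is.na(model$band)) {
    stop("model carries no transform/band annotation", call. = FALSE)
  }
  tds <- apply_transform(dataset, model$transform,
                         derivative_mode = derivative_mode,
                         on_singular = "mask")
  j <- match(model$band, tds$wavelengths)
  if (is.na(j)) stop("band ", model$band, " nm outside the dataset grid",
                     call. = FALSE)
  x <- tds$values[, j]
  yhat <- predict(model, x, on_domain = "na")
  ok <- !is.na(yhat)
  if (sum(ok) < 2L) stop("fewer than 2 evaluable samples", call. = FALSE)
  y <- tds$lac
  structure(
    list(r2 = .r2(y, yhat),
         r2_cor = suppressWarnings(stats::cor(y[ok], yhat[ok]))^2,
         rmse = rmse(y[ok], yhat[ok]),
         n = sum(ok), n_domain_violations = sum(!ok),
         stratum = stratum,
         transform = model$transform, band = model$band,
         family = model$family),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s @ %g nm (%s)%s: R2 = %.3f, RMSE = %.4g mg/g, n = %d\n",
    x$transform, x$band, x$family,
    if (is.na(x$stratum)) "" else paste0(", stratum ", x$stratum),
    x$r2, x$rmse, x$n))
  invisible(x)
}

#' Restrict a dataset to a low-anthocyanin stratum
#'
#' Keeps the samples with LAC strictly below `threshold` (default 20 mg/g,
#' the range covering most plant species), for stratified re-calibration or
#' re-evaluation.
#'
#' @param dataset A [spectral_dataset()].
#' @param threshold_mg_per_g Positive threshold (default 20).
#' @return The subset `spectral_dataset`.
#' @export
stratify_below <- function(dataset, threshold_mg_per_g = 20) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (threshold_mg_per_g <= 0) stop("threshold must be > 0", call. = FALSE)
  keep <- dataset$lac < threshold_mg_per_g
  if (!any(keep)) {
    stop(sprintf("empty stratum: no sample below %g mg/g",
                 threshold_mg_per_g), call. = FALSE)
  }
  subset_samples(dataset, which(keep))
}
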