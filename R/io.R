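#' Read a spectral table
#'
#' Reads paired spectra and anthocyanin contents from CSV. Two dialects are
#' accepted: wide (`sample_id, lac_mg_per_g, w350, w351, ...`, one row per
#' leaf) and long (`sample_id, lac_mg_per_g, wavelength_nm, reflectance`).
#' Wavelength columns must form a strictly increasing, constant-step grid.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` (default) or `"long"`.
#' @param on_invalid Handling of reflectance outside \[0, 1\]: `"clip"`
#'   (default) clips to \[1e-6, 1 - 1e-6\] with a warning, so the log-based
#'   transforms stay defined; `"reject"` drops the offending samples with a
#'   warning naming them; `"error"` stops, naming the first offending sample.
#' @return A [spectral_dataset()].
#' @export
read_spectral_table <- function(path, dialect = c("wide", "long"),
                                on_invalid = c("clip", "reject", "error")) {
  dialect <- match.arg(dialect)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "lac_mg_per_g", "wavelength_nm", "reflectance")
    if (!all(need %in% names(df))) {
      stop("long dialect requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    ids <- unique(df$sample_id)
    w <- sort(unique(df$wavelength_nm))
    .check_grid(w)
    m <- matrix(NA_real_, length(ids), length(w),
                dimnames = list(ids, paste0("w", w)))
    m[cbind(match(df$sample_id, ids), match(df$wavelength_nm, w))] <-
      df$reflectance
    if (anyNA(m)) stop("long table is not a complete sample x wavelength grid",
                       call. = FALSE)
    lac <- df$lac_mg_per_g[match(ids, df$sample_id)]
    return(.validate_reflectance(w, m, lac, ids, on_invalid))
  }
  if (!"sample_id" %in% names(df)) stop("missing sample_id column",
                                        call. = FALSE)
  if (!"lac_mg_per_g" %in% names(df)) stop("missing lac_mg_per_g (LAC) column",
                                           call. = FALSE)
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  if (!length(wcols)) stop("no wavelength columns (w<nm>) found",
                           call. = FALSE)
  w <- as.numeric(sub("^w", "", wcols))
  ord <- order(w)
  w <- w[ord]; wcols <- wcols[ord]
  .check_grid(w)
  m <- as.matrix(df[, wcols, drop = FALSE])
  if (!is.numeric(m)) {
    num <- vapply(df[wcols], is.numeric, logical(1))
    badrow <- which(apply(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))), 1L, any))
    stop("non-numeric reflectance for sample(s): ",
         paste(df$sample_id[utils::head(badrow, 5L)], collapse = ", "),
         call. = FALSE)
  }
  .validate_reflectance(w, m, df$lac_mg_per_g, df$sample_id, on_invalid)
}

.validate_reflectance <- function(w, m, lac, ids, on_invalid,
                                  eps = 1e-6) {
  if (anyNA(lac) || !is.numeric(lac)) {
    stop("non-numeric or missing LAC values", call. = FALSE)
  }
  bad_cell <- is.na(m) | m < 0 | m > 1
  if (any(bad_cell)) {
    bad_samples <- ids[apply(bad_cell, 1L, any)]
    if (on_invalid == "error") {
      stop("reflectance outside [0,1] (or missing) for sample(s): ",
           paste(utils::head(bad_samples, 5L), collapse = ", "),
           call. = FALSE)
    }
    if (on_invalid == "reject") {
      warning("rejecting ", length(bad_samples),
              " sample(s) with invalid reflectance: ",
              paste(utils::head(bad_samples, 5L), collapse = ", "),
              call. = FALSE)
      keep <- !apply(bad_cell, 1L, any)
      if (!any(keep)) stop("all samples rejected", call. = FALSE)
      m <- m[keep, , drop = FALSE]; lac <- lac[keep]; ids <- ids[keep]
    }
  }
  if (on_invalid == "clip") {
    n_clip <- sum(m < eps | m > 1 - eps, na.rm = TRUE)
    if (n_clip > 0) {
      warning("clipped ", n_clip, " reflectance value(s) into [",
              format(eps), ", 1 - ", format(eps), "]", call. = FALSE)
    }
    m <- pmin(pmax(m, eps), 1 - eps)
  }
  spectral_dataset(w, m, lac, ids, kind = "P")
}

#' Write a spectral table
#'
#' Emits the wide CSV dialect read back bit-identically by
#' [read_spectral_table()] (full precision, no quoting).
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(sample_id = dataset$sample_id,
                   lac_mg_per_g = dataset$lac,
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
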