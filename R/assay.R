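#' pH-differential assay measurement
#'
#' Bundles the spectrophotometer readings and dilution bookkeeping of the
#' pH-differential method for total monomeric anthocyanin: absorbances at
#' 510 and 700 nm in pH 1.0 and pH 4.5 buffers, the dilution factor D, the
#' final volume V (ml) and the dry material mass G (mg). The default
#' constants are the cyanidin 3-glucoside molar absorbance
#' e = 26,900 ml/(mmol cm), cell path length L = 1 cm and molecular weight
#' MW = 449.2 Da.
#'
#' @param a510_ph1,a700_ph1,a510_ph45,a700_ph45 Absorbances (>= 0); may be
#'   vectors for a batch of samples.
#' @param dilution Dilution factor D (>= 1, default 1).
#' @param volume_ml Final volume V in ml (default 25).
#' @param mass_mg Dry material G in mg (default 1).
#' @param e Molar absorbance, ml/(mmol cm) (default 26900).
#' @param path_cm Cell path length L, cm (default 1).
#' @param mw Molecular weight, Da (default 449.2).
#' @return An object of class `"assay_measurement"`.
#' @export
assay_measurement <- function(a510_ph1, a700_ph1, a510_ph45, a700_ph45,
                              dilution = 1, volume_ml = 25, mass_mg = 1,
                              e = 26900, path_cm = 1, mw = 449.2) {
  abs_all <- c(a510_ph1, a700_ph1, a510_ph45, a700_ph45)
  if (any(abs_all < 0, na.rm = TRUE)) stop("absorbances must be >= 0",
                                           call. = FALSE)
  if (any(volume_ml <= 0) || any(mass_mg <= 0)) {
    stop("volume and mass must be > 0", call. = FALSE)
  }
  if (any(dilution < 1)) stop("dilution factor must be >= 1", call. = FALSE)
  if (e <= 0 || path_cm <= 0 || mw <= 0) stop("constants must be > 0",
                                              call. = FALSE)
  structure(
    list(a510_ph1 = a510_ph1, a700_ph1 = a700_ph1,
         a510_ph45 = a510_ph45, a700_ph45 = a700_ph45,
         dilution = dilution, volume_ml = volume_ml, mass_mg = mass_mg,
         e = e, path_cm = path_cm, mw = mw),
    class = "assay_measurement"
  )
}

#' pH-differential absorbance difference
#'
#' `Abs = (A510 - A700)_pH1.0 - (A510 - A700)_pH4.5`. The flavylium cation
#' absorbs at pH 1.0 but not at pH 4.5, so this difference isolates the
#' monomeric anthocyanin signal; A700 corrects for haze.
#'
#' @param m An [assay_measurement()].
#' @return Absorbance difference (vectorised over batch measurements). A
#'   negative value signals an assay anomaly and is returned with a warning.
#' @export
abs_difference <- function(m) {
  stopifnot(inherits(m, "assay_measurement"))
  out <- (m$a510_ph1 - m$a700_ph1) - (m$a510_ph45 - m$a700_ph45)
  if (any(out < 0, na.rm = TRUE)) {
    warning("negative pH-differential absorbance (assay anomaly)",
            call. = FALSE)
  }
  out
}

#' Total anthocyanin content from a pH-differential measurement
#'
#' \deqn{content = \frac{Abs}{e \, L} \times MW \times D \times \frac{V}{G}}
#' expressed as cyanidin 3-glucoside equivalents. The formula is applied
#' exactly as written, with G the dry-material mass in mg; reconciling the
#' result to a per-gram-fresh-leaf basis (extraction yield, concentrate
#' mass) is left to the caller.
#'
#' @param m An [assay_measurement()], or a precomputed numeric `Abs`
#'   together with the remaining arguments.
#' @param ... When `m` is numeric: `dilution`, `volume_ml`, `mass_mg`, `e`,
#'   `path_cm`, `mw` as in [assay_measurement()].
#' @return Anthocyanin content, mg/g (vectorised).
#' @export
#' @examples
#' m <- assay_measurement(0.369, 0.05, 0.08, 0.03)
#' anthocyanin_content(m)
anthocyanin_content <- function(m, ...) {
  if (is.numeric(m)) {
    args <- list(...)
    defaults <- list(dilution = 1, volume_ml = 25, mass_mg = 1,
                     e = 26900, path_cm = 1, mw = 449.2)
    p <- utils::modifyList(defaults, args)
    ab <- m
    return(ab / (p$e * p$path_cm) * p$mw * p$dilution *
             p$volume_ml / p$mass_mg)
  }
  stopifnot(inherits(m, "assay_measurement"))
  ab <- abs_difference(m)
  ab / (m$e * m$path_cm) * m$mw * m$dilution * m$volume_ml / m$mass_mg
}

#' Batch pH-differential computation
#'
#' Evaluates the assay for a table of measurements, one row per sample.
#'
#' @param df Data frame with columns `sample_id`, `a510_ph1`, `a700_ph1`,
#'   `a510_ph45`, `a700_ph45` and optionally `dilution`, `volume_ml`,
#'   `mass_mg` (defaults 1, 25, 1).
#' @return The input with added columns `abs_diff` and `lac_mg_per_g`,
#'   joinable to spectral tables by `sample_id`.
#' @export
assay_batch <- function(df) {
  need <- c("sample_id", "a510_ph1", "a700_ph1", "a510_ph45", "a700_ph45")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$dilution)) df$dilution <- 1
  if (is.null(df$volume_ml)) df$volume_ml <- 25
  if (is.null(df$mass_mg)) df$mass_mg <- 1
  m <- assay_measurement(df$a510_ph1, df$a700_ph1, df$a510_ph45,
                         df$a700_ph45, dilution = df$dilution,
                         volume_ml = df$volume_ml, mass_mg = df$mass_mg)
  df$abs_diff <- suppressWarnings(abs_difference(m))
  df$lac_mg_per_g <- df$abs_diff / (m$e * m$path_cm) * m$mw * df$dilution *
    df$volume_ml / df$mass_mg
  df
}
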