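#' Configuration of the leaf-spectrum simulator
#'
#' Defines the statistical structure of a simulated purple-leaf dataset:
#' N leaves on the 350--2500 nm grid at 1-nm step, whose visible-band
#' absorption is driven by anthocyanin content via a saturating
#' Beer--Lambert response, with weak chlorophyll and leaf-moisture
#' confounders and instrument noise.
#'
#' Defaults mirror the purple-corn study population: anthocyanin content
#' uniform on 0.09--44.3 mg/g, chlorophyll 0.056 +/- 0.026 mg/g (truncated
#' at 0), moisture 8.6 +/- 1.76 % clipped to 6--12 %. The anthocyanin
#' feature is a Gaussian absorption centred at 650 nm (width 45 nm) inside
#' the sensitive 570--685 nm window; its optical depth saturates as
#' `1 - exp(-LAC/s)` with `s` chosen so half-saturation falls near 25 mg/g,
#' which reproduces the qualitative observation that calibration behaves
#' better below 20 mg/g. Noise levels reflect a 10-scan-averaged
#' spectroradiometer with an integrating sphere: 0.5 % multiplicative and
#' 0.001 additive reflectance noise. Because such instruments resolve about
#' 3 nm optically while reporting a 1-nm grid, noise is spectrally smooth:
#' the noise fields are white noise convolved with a unit-variance Gaussian
#' kernel of standard deviation `noise_corr_nm` (3 nm default; 0 gives
#' white noise). Smooth noise is what lets first-order differentials
#' enhance, rather than destroy, the trait correlation.
#'
#' @param n_samples Number of leaves (default 500).
#' @param lac_range Anthocyanin range, mg/g, sampled uniformly
#'   (default `c(0.09, 44.3)`).
#' @param chl_mean,chl_sd Chlorophyll distribution, mg/g (0.056, 0.026).
#' @param moisture_mean,moisture_sd Leaf moisture, percent (8.6, 1.76),
#'   clipped to `moisture_clip`.
#' @param moisture_clip Moisture bounds, percent (default `c(6, 12)`).
#' @param antho_center,antho_width Anthocyanin absorption feature, nm
#'   (650, 45).
#' @param antho_absorptivity Peak optical depth of the fully saturated
#'   anthocyanin feature (default 2).
#' @param saturation Saturation constant `s`, mg/g (default
#'   `25 / log(2)`: half-saturation at 25 mg/g).
#' @param chl_center,chl_width,chl_absorptivity Chlorophyll feature: 680 nm,
#'   25 nm, optical depth per mg/g (default 3).
#' @param water_centers,water_width,water_absorptivity Water features:
#'   1450 and 1940 nm, 60 nm, optical depth per percent moisture
#'   (default 0.05).
#' @param noise_additive_sd,noise_multiplicative_sd Reflectance noise
#'   (0.001 additive; 0.005 relative).
#' @param noise_corr_nm Spectral correlation length of the noise, nm
#'   (Gaussian kernel sd; default 3, 0 = white noise).
#' @param wavelengths Grid, nm (default `350:2500`).
#' @param null_mode If TRUE, the anthocyanin term is omitted from the
#'   spectra while LAC is still drawn, giving zero spectrum--trait coupling
#'   (for null screening experiments).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples = 500,
                              lac_range = c(0.09, 44.3),
                              chl_mean = 0.056, chl_sd = 0.026,
                              moisture_mean = 8.6, moisture_sd = 1.76,
                              moisture_clip = c(6, 12),
                              antho_center = 650, antho_width = 45,
                              antho_absorptivity = 2,
                              saturation = 25 / log(2),
                              chl_center = 680, chl_width = 25,
                              chl_absorptivity = 3,
                              water_centers = c(1450, 1940),
                              water_width = 60,
                              water_absorptivity = 0.05,
                              noise_additive_sd = 0.001,
                              noise_multiplicative_sd = 0.005,
                              noise_corr_nm = 3,
                              wavelengths = 350:2500,
                              null_mode = FALSE,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  if (cfg$lac_range[1] >= cfg$lac_range[2]) {
    stop("lac_range must be increasing", call. = FALSE)
  }
  if (any(c(cfg$chl_sd, cfg$moisture_sd, cfg$noise_additive_sd,
            cfg$noise_multiplicative_sd, cfg$noise_corr_nm) < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  .check_grid(cfg$wavelengths)
  centers <- c(cfg$antho_center, cfg$chl_center, cfg$water_centers)
  if (any(centers < min(cfg$wavelengths) | centers > max(cfg$wavelengths))) {
    stop("feature centers must lie inside the wavelength grid", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# unit-peak Gaussian absorption shape
.gauss <- function(w, center, width) exp(-0.5 * ((w - center) / width)^2)

# smooth pigment-free leaf baseline: low visible plateau, red-edge rise
# around 690-750 nm, NIR plateau ~0.45
.leaf_baseline <- function(w) {
  0.10 + 0.35 * stats::plogis((w - 720) / 12)
}

# n x p field of unit-variance Gaussian noise, spectrally smoothed with a
# Gaussian kernel (sd corr_nm in band units); corr_nm = 0 gives white noise
.noise_field <- function(n, p, corr_nm, step = 1) {
  if (corr_nm <= 0) return(matrix(stats::rnorm(n * p), n, p))
  c_bands <- corr_nm / step
  m <- max(1L, ceiling(4 * c_bands))
  k <- stats::dnorm(seq(-m, m), 0, c_bands)
  k <- k / sqrt(sum(k^2))  # unit output variance
  z <- matrix(stats::rnorm(n * (p + 2L * m)), n, p + 2L * m)
  t(apply(z, 1L, function(row) {
    stats::convolve(row, rev(k), type = "filter")
  }))
}

#' Simulate a paired spectrum/anthocyanin dataset
#'
#' For each leaf, anthocyanin content (LAC), chlorophyll and moisture are
#' drawn from the configured distributions, and reflectance is built as
#' \deqn{P(\lambda) = B(\lambda)\,\exp\{-k_a (1 - e^{-LAC/s}) g_a(\lambda)
#'   - k_c\,chl\,g_c(\lambda) - k_w\,moist\,[g_{1450}(\lambda) +
#'   g_{1940}(\lambda)]\}}
#' with Gaussian absorption shapes g and a smooth leaf baseline B, then
#' multiplicative and additive noise are applied and the result is clipped
#' into (1e-6, 1 - 1e-6). In `null_mode` the anthocyanin term is omitted,
#' leaving no spectrum--trait coupling.
#'
#' @param config A [simulation_config()].
#' @return A [spectral_dataset()] of kind `"P"` with an attribute
#'   `"config"` recording the generating configuration.
#' @export
#' @examples
#' d <- generate_dataset(simulation_config(n_samples = 10, seed = 42))
#' d
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  w <- as.numeric(config$wavelengths)
  p <- length(w)
  n <- config$n_samples
  base <- .leaf_baseline(w)
  g_a <- .gauss(w, config$antho_center, config$antho_width)
  g_c <- .gauss(w, config$chl_center, config$chl_width)
  g_w <- rowSums(vapply(config$water_centers,
                        function(cc) .gauss(w, cc, config$water_width),
                        numeric(p)))
  withr::with_seed(as.integer(config$seed), {
    lac <- stats::runif(n, config$lac_range[1], config$lac_range[2])
    chl <- pmax(stats::rnorm(n, config$chl_mean, config$chl_sd), 0)
    moist <- pmin(pmax(stats::rnorm(n, config$moisture_mean,
                                    config$moisture_sd),
                       config$moisture_clip[1]), config$moisture_clip[2])
    depth_a <- if (config$null_mode) rep(0, n) else
      config$antho_absorptivity * (1 - exp(-lac / config$saturation))
    # optical depth matrix: samples x bands
    od <- outer(depth_a, g_a) +
      outer(config$chl_absorptivity * chl, g_c) +
      outer(config$water_absorptivity * moist, g_w)
    refl <- sweep(exp(-od), 2L, base, `*`)
    step <- if (p > 1L) w[2L] - w[1L] else 1
    noise_m <- config$noise_multiplicative_sd *
      .noise_field(n, p, config$noise_corr_nm, step)
    noise_a <- config$noise_additive_sd *
      .noise_field(n, p, config$noise_corr_nm, step)
    refl <- refl * (1 + noise_m) + noise_a
    refl <- pmin(pmax(refl, 1e-6), 1 - 1e-6)
    ds <- spectral_dataset(w, refl, lac,
                           sample_id = sprintf("SIM%04d", seq_len(n)),
                           kind = "P")
    attr(ds, "config") <- config
    ds
  })
}

#' Simulate pH-differential assay measurements consistent with a dataset
#'
#' Constructs, for every sample, a set of absorbances whose
#' pH-differential evaluation ([anthocyanin_content()]) returns the
#' sample's LAC up to additive assay noise (`noise_sd`, mg/g). The pH 4.5
#' and A700 readings are small constant backgrounds; the pH 1.0 A510
#' reading carries the anthocyanin signal.
#'
#' @param dataset A [spectral_dataset()] (its `lac` values are used).
#' @param noise_sd Assay noise on the content scale, mg/g (default 0).
#' @param seed Integer seed for the noise draw.
#' @return A data frame of batch measurements: `sample_id`, the four
#'   absorbances, `dilution`, `volume_ml`, `mass_mg`.
#' @export
generate_assay_table <- function(dataset, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  e <- 26900; L <- 1; mw <- 449.2; D <- 1; V <- 25; G <- 1
  lac <- dataset$lac
  noisy <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     lac + stats::rnorm(length(lac), 0, noise_sd))
  } else lac
  # a cuvette cannot absorb negatively: floor the implied content at zero
  abs_needed <- pmax(noisy, 0) * e * L * G / (mw * D * V)
  a700_ph1 <- 0.04; a510_ph45 <- 0.06; a700_ph45 <- 0.03
  data.frame(sample_id = dataset$sample_id,
             a510_ph1 = abs_needed + a700_ph1 + (a510_ph45 - a700_ph45),
             a700_ph1 = a700_ph1,
             a510_ph45 = a510_ph45,
             a700_ph45 = a700_ph45,
             dilution = D, volume_ml = V, mass_mg = G,
             stringsAsFactors = FALSE)
}
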