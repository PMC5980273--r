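---
title: "Calibrating foliar anthocyanin content from leaf reflectance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating foliar anthocyanin content from leaf reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthospec)
```

## The problem

Anthocyanins are the flavylium pigments that colour purple-leaved crops.
Their reference quantification — the pH-differential assay or HPLC — is
destructive and slow, so breeders and processors want a calibration that
reads the content off a leaf reflectance spectrum instead. `anthospec`
implements the classical single-band empirical calibration workflow for
this problem: re-express the reflectance spectrum through a battery of
transforms, find for each transform the wavelength most correlated with
the measured content, fit a small set of curve families at that wavelength,
and keep the best-fitting curve as the calibration.

The workflow is intentionally simple — one predictor band per transform,
five closed-form curve shapes — because that is the procedure whose
behaviour the package is meant to reproduce and study, not a
state-of-the-art chemometric pipeline.

## Data model

A `spectral_dataset` holds N leaf spectra on a shared strictly-increasing
constant-step wavelength grid (1 nm for ASD-class field spectrometers,
350–2500 nm) together with the measured leaf anthocyanin content
(LAC, mg/g cyanidin 3-glucoside equivalents). Replicate scans of one leaf
are averaged pointwise (`average_replicates()`) before analysis.
Reflectance is validated into [0, 1]; by default values are clipped into
[1e-6, 1 − 1e-6] at read time (with a warning) so that the logarithmic
transforms below stay finite. Strict and reject modes are available when
clipping would hide an instrument problem.

## The transform battery

Eight re-expressions of reflectance P are screened: P, 1/P, lg P,
1/lg P, and the first-order differential of each. Two conventions matter:

* **lg is the base-10 logarithm.** This is the standard chemometrics
  reading of "lg"; a natural log would rescale coefficients but, being a
  positive multiple, could not change any correlation or any selected
  band.
* **The differential divides the backward difference by 2Δλ:** at
  wavelength λ~i~ the differential is
  [v(λ~i~) − v(λ~i−1~)] / (2Δλ), attached to λ~i~, so the output grid
  drops its first band. This is *half* the usual backward difference.
  Because Pearson correlation and R² are invariant to positive scaling,
  the factor of two is irrelevant to band selection and to goodness of
  fit; only the printed coefficients of the fitted equations absorb it.
  A genuine central-difference mode
  ([v(λ~i+1~) − v(λ~i−1~)] / (2Δλ), both end bands dropped) is available
  via `derivative_mode = "central"`. Note that the two stencils are
  *different estimators*, not rescalings of one another: the backward
  form estimates the slope half a band to the left of where the central
  form does, so on a 1-nm grid the selected sensitive band of a
  derivative transform can legitimately differ by about one band between
  modes. Rescaling-invariance is exact; stencil-invariance is only
  approximate.

## Screening

Screening restricts the grid to 400–1400 nm by default: the shortwave
infrared beyond 1400 nm is dominated by the 1450/1940 nm water
absorptions and by instrument noise, and the region below 400 nm by
detector noise. For each transform the per-band Pearson correlation with
LAC is computed (`correlation_spectrum()`), and the **sensitive band** is
the wavelength of maximal |r| (`select_sensitive_band()`), ties broken
deterministically toward the smaller wavelength. Bands where a transform
is undefined for any sample are marked missing (`NA`) and excluded from
that transform's screening only — they are never reported as r = 0.
About a thousand bands are screened per transform and no multiplicity
correction is applied (none is part of the procedure being modelled);
the screening report carries `n_bands_screened` so users can judge the
selection effect themselves, and the null-mode generator (below) provides
the empirical yardstick for what maximal |r| pure selection noise
produces.

## Model fitting and selection

At each transform's sensitive band, five families are fitted with the
band value X as predictor and LAC Y as response: Y = aX + b,
Y = aX² + bX + c, Y = aX^b, Y = a·e^{bX}, Y = a·ln(X) + b. Linear,
quadratic and logarithmic fits are ordinary least squares in closed form.
Power and exponential fits are Levenberg–Marquardt nonlinear least squares
(`minpack.lm`) on the original Y scale, started from the log-linearised
closed form and internally parameterised through log a — fitted
intercepts can span many orders of magnitude, and the log
parameterisation keeps the optimiser conditioned. A refinement is never
accepted if it ends with a larger residual sum of squares than its start,
so the nonlinear route can only improve on the log-space solution.

R² is defined as 1 − SS~res~/SS~tot~ **on the original scale** for every
family, which is the only definition comparable across families; for
power and exponential fits the log-space R² of the linearised regression
(what spreadsheet trendlines report) is also carried as `r2_log`, but
selection uses the original scale. Points outside a family's domain
(X ≤ 0 for power and logarithmic) are excluded per family; if more than
10 % of points are excluded (configurable) the family is marked
*skipped* rather than fitted — differential transforms are often largely
negative, and a power law fitted to a sliver of the data would be
meaningless. The best model maximises R², with ties broken toward fewer
coefficients and then toward the lower band.

## Validation

The dataset is split uniformly at random (seeded; optionally stratified
by LAC quartile) into training and validation sets, 400/100 at N = 500
by default. Held-out performance is reported as RMSE
(√(Σ(LAC~i~ − PLAC~i~)²/N), mg/g) and as both
R² = 1 − SS~res~/SS~tot~ (which can be negative out of sample) and the
squared observed-predicted correlation. A low-content stratum
(LAC < 20 mg/g by default, the range covering most species) is
re-analysed; `stratum_mode = "refit"` (default) re-runs screening and
fitting inside the stratum, `"evaluate"` merely re-scores the full-range
model there.

## The simulator

`generate_dataset()` provides paired spectra/LAC data with the
statistical structure the workflow assumes, so every stage is testable
without a field campaign. Per leaf it draws LAC uniform on
0.09–44.3 mg/g, chlorophyll 0.056 ± 0.026 mg/g (floored at 0) and
moisture 8.6 ± 1.76 % (clipped to 6–12 %), and builds

P(λ) = B(λ) · exp{ −k~a~ (1 − e^{−LAC/s}) g(λ; 650, 45)
− k~c~·chl·g(λ; 680, 25) − k~w~·moist·[g(λ; 1450, 60) + g(λ; 1940, 60)] }

with unit-peak Gaussian shapes g, then applies multiplicative (0.5 %) and
additive (0.001) noise and clips into (1e-6, 1 − 1e-6). B(λ) is a smooth
pigment-free leaf baseline: a 0.10 visible plateau rising through a
logistic red edge near 720 nm to a 0.45 NIR plateau.

Choices worth making explicit:

* **Saturating Beer–Lambert response.** The anthocyanin optical depth is
  k~a~(1 − e^{−LAC/s}) with s = 25/ln 2, i.e. half-saturation near
  25 mg/g and k~a~ = 2 at full saturation. Saturation is what makes the
  low-content stratum genuinely easier to calibrate — the qualitative
  behaviour the validation stage is designed to expose. A purely linear
  absorbance would make stratification pointless.
* **Spectrally correlated noise.** Field spectroradiometers resolve
  roughly 3 nm optically while reporting a 1-nm interpolated grid, so
  per-band noise is smooth, not white: both noise fields are white noise
  convolved with a unit-variance Gaussian kernel of 3 nm standard
  deviation (`noise_corr_nm`; 0 recovers white noise). This matters
  scientifically: against white 1-nm noise a first difference is noise
  amplification and the derivative transforms lose all trait
  correlation, whereas against smooth noise they enhance it — the
  behaviour single-band derivative screening relies on.
* **Uniform LAC.** The source population's distribution is unknown
  beyond its range and mean; uniform sampling over the printed range is
  the least committal choice and deliberately does not match the
  reported mean of 17.8 mg/g.
* **Feature placement.** The anthocyanin feature sits at 650 nm (width
  45 nm), inside the 570–685 nm window where anthocyanin sensitivity is
  expected; chlorophyll at 680 nm overlaps it deliberately, as the weak
  confounder it is at a 300:1 content ratio.
* **`null_mode`** omits the anthocyanin term while still drawing LAC,
  giving an exact no-coupling reference against which "maximal |r| over
  ~8000 screened band×transform combinations" can be judged.

What the simulator does **not** emulate: radiative-transfer leaf optics
(no PROSPECT-style plate model), scattering anisotropy, specular
artefacts, sample-to-sample baseline variation beyond the modelled
constituents, or instrument drift. Passing tests on simulated data
therefore demonstrate that the pipeline recovers structure *of the kind
it assumes*; they say nothing about how strong that structure is in real
leaves.

A companion generator, `generate_assay_table()`, inverts the
pH-differential formula to emit absorbance quadruples whose evaluation
round-trips each sample's LAC (optionally with assay noise, floored at
zero absorbance), so the wet-chemistry module can be tested end to end
against the spectral module.

## The pH-differential module

`anthocyanin_content()` implements the standard total-monomeric
computation, content = Abs/(e·L) · MW · D · V/G, with
Abs = (A510 − A700)~pH1.0~ − (A510 − A700)~pH4.5~, e = 26,900
ml/(mmol·cm), L = 1 cm and MW = 449.2 Da for cyanidin 3-glucoside. The
formula is applied exactly as conventionally written, with G the
dry-material mass in mg; its dimensional bookkeeping yields content per
unit of dried concentrate, and reconciling that to a per-gram-of-leaf
basis (extraction yield) is deliberately left to the caller rather than
silently guessed. Negative Abs is returned with a warning — it indicates
an assay anomaly, not a computational error.

## Numerical and degenerate-input policy

* Constant trait → error ("trait has zero variance"); fewer than 3
  samples → error; zero-variance band → missing marker.
* Ties in |r| → lowest wavelength; ties in R² → fewest coefficients,
  then lowest band. Both are deterministic by design so that identical
  configuration and seeds reproduce every artifact byte for byte (all
  randomness flows through explicitly seeded draws that leave the
  session RNG untouched).
* Reflectance exactly 0 or 1: `strict` errors, `mask` disables the band
  for log transforms only, and the reader's default clip keeps such
  values representable while warning.
* Nonlinear fits: 200 iteration cap, fallback to the log-linearised
  start on optimiser failure, never-worse-than-start guarantee.

## Problem sizes

The test-suite simulations use 25–500 leaves on the full 1-nm grid (or a
coarser 50-nm grid where only the trait pairing matters), sizes chosen so
the complete suite exercises every stage, including two full 500-leaf
end-to-end runs, in well under a minute on a laptop-class machine. The
reproduction script (`scripts/acceptance.R`) runs the canonical
500-leaf / 400-train / 100-validation design plus a 400-leaf null
screening.

## Known limitations

* Single-band, single-transform calibration only; no multivariate or
  multi-band indices, regularisation, cross-validation or bootstrap
  uncertainty — these are outside the modelled procedure.
* The sensitive band is a point estimate of a selection over ~1000
  correlated tests; on flat correlation plateaus (notably the derivative
  transforms) it can move by a band or two under resampling or a change
  of difference stencil.
* Simulated-data performance (R² ≈ 0.99 at default noise) is far above
  what field data yield; the simulator's purpose is structural testing,
  not effect-size realism.
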