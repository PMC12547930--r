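---
title: "Rectal-wall radiomics and the timing of adaptive re-planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rectal-wall radiomics and the timing of adaptive re-planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rectomics)
```

## The problem

Prostate radiotherapy is delivered over 20 or 37 daily fractions under daily
image guidance (megavoltage CT on helical TomoTherapy). The daily images are
normally used only for positioning, yet they sample the rectal wall - the
organ at risk for late rectal bleeding - every treatment day. `rectomics`
implements a longitudinal radiomics analysis of those images: texture
features of the rectal wall are extracted from the planning CT and from each
fraction's MVCT, aggregated into weekly time points, and used to model the
binary endpoint *grade >= 1 rectal bleeding at two years*. Comparing model
performance across time points identifies the earliest week at which an
adaptive re-plan would be best informed by the accumulating image signal.

Two regimens are handled: 74 Gy in 37 fractions (7 treatment weeks; week 7
covers fractions 31-37) and 60 Gy in 20 fractions (4 weeks of 5 fractions).
Patients are always stratified by regimen, since dose per fraction and
course length both change the biology and the available time points.

## Region of interest and subimages

All processing is slice-wise. The rectum contour (a planar polygon in pixel
coordinates) is rasterised with a centre-inclusive rule: a pixel belongs to
the mask iff its centre lies inside the polygon or on its boundary, with
pixel centres at integer (row, col) positions, 0-based. This rule is
deliberate: it is unambiguous and directly checkable against an exhaustive
point-in-polygon oracle.

The *rectal wall* is the 2-pixel ring obtained by subtracting the double
morphological erosion (3x3 square structuring element) from the filled
rectum mask - the discrete realisation of "expanding the contour inwards by
2 pixels". If two erosions empty the mask (a very small rectum cross
section), the whole mask is used and a warning is emitted.

Along the ring, 8x8-pixel subimages are tiled at 1-pixel intervals: one
window per wall pixel, anchored 3 pixels up and left, so the generating
pixel sits in the window's central 2x2 block. Where the 2-pixel band runs
locally straight, the two band pixels' windows each span 3 pixels beyond the
band on either side (3 + 2 + 3 = 8). The window count per wall pixel (as
opposed to per boundary-arc step) only rescales the number of vectors that
enter the average, not the average itself. Windows crossing the slice
border are dropped rather than padded - padding would inject artificial
texture into every border window. Anchors are de-duplicated and ordered
row-major so tiling is deterministic.

## The 118-feature catalogue

Each subimage yields 118 features in a fixed, documented order
(`featureCatalogue()`): 23 first-order (FOS), 25 grey-level co-occurrence
(GLCM), 16 run-length (GLRLM), 16 size-zone (GLSZM), 16 distance-zone
(GLDZM), 5 neighbourhood grey-tone difference (NGTDM) and 17 neighbouring
grey-level dependence (NGLDM) features, following the IBSI reference
definitions. These family cardinalities sum exactly to 118 and cover all
indices used in the package's report notation (e.g. `W1:GLDZM14`).

Numerical conventions, all unit-tested so aggregation never propagates
non-finite values:

* **Discretisation.** Fixed bin number (default `Ng = 8`) over each
  window's own min-max range; 64 pixels over 8 levels gives ~8 pixels per
  level. A constant window maps to level 1. Discretisation is invariant
  under affine intensity rescaling, so all discretised families are
  intensity-scale-free; the FOS location/scale statistics (mean, variance,
  percentiles, ...) are computed on raw intensities and carry the HU scale.
  FOS mode, entropy, uniformity and the four histogram-gradient features
  use the discretised histogram.
* **Geometry.** 2D computation with 4 directions (0, 45, 90, 135 degrees)
  at distance 1 for GLCM/GLRLM, features computed per direction and
  averaged; 8-connected zones for GLSZM/GLDZM; 8-neighbourhoods for
  NGTDM/NGLDM with the NGLDM coarseness parameter alpha = 0. GLDZM zone
  distance is the minimum chessboard distance of a zone pixel to outside
  the 8x8 window (border pixels = 1): the window border acts as the ROI
  border.
* **Degenerate inputs.** For constant windows: skewness = kurtosis =
  coefficient of variation = 0, GLCM correlation and both information
  correlations = 0, NGTDM coarseness saturates at 1e6, histogram gradients
  are 0. Percentiles use the standard linear-interpolation definition
  (type 7).

The extractor is compiled (Rcpp), as is usual for radiomics engines; an
independent R implementation of every family formula, operating on the
matrix structures returned by `textureMatrix()`, is kept in the package and
tested against both the compiled path and exhaustive brute-force
enumeration oracles.

## Temporal aggregation

Per-window vectors are averaged over all subimages and slices of a scan
(plain arithmetic mean), giving one 118-vector per scan. MVCT scan vectors
are then averaged within treatment weeks; the planning CT is its own `CT`
time point. The feature table is a `SummarizedExperiment` with features as
rows and (patient, time point) cells as columns. Patients with no scans in
a week simply lack that column; they are dropped from models at that time
point and listed in a roster. Week averages use whatever fractions are
available - daily imaging gaps are tolerated and logged, not imputed.

## Modelling chain

Within each regimen:

1. **Split.** 75:25 train/test, stratified by the binary endpoint. The
   test size is round-half-up(0.25 N) with round-half-up(0.25 n_pos)
   positive patients; this rounding uniquely reproduces both published
   split tables (110 -> 82/28 and 77 -> 58/19).
2. **Standardise.** z-scores with training-set mean and *population*
   standard deviation; test data transformed with training parameters.
   Constant training features are dropped with a log message.
3. **Screen.** Two-sided Mann-Whitney U per feature (exact enumeration
   when both groups have <= 8 members and no ties; normal approximation
   with tie correction otherwise). The screen ranks features and feeds the
   pruning step; it does not itself drop features.
4. **Prune.** All feature pairs with training |Spearman rho| >= 0.8 are
   processed in descending |rho| (ties broken lexicographically); the less
   significant member (larger screen p; ties to the lexicographically
   later name) is removed, and pairs involving removed features are
   skipped. The surviving set provably contains no pair at or above the
   threshold, and this is re-asserted on every run.
5. **Fit.** Penalised logistic regression (glmnet) with elastic-net mixing
   0.5 and the inverse strength C tuned over 500 log-spaced values in
   [1e-4, 1e3] by stratified 5-fold cross-validation maximising mean fold
   AUC; ties resolve toward the stronger penalty. C maps to the glmnet
   penalty as lambda = 1/(n C), the exact correspondence between the two
   parameterisations of the same objective. Fold AUC of a constant
   predictor is defined as 0.5.
6. **Evaluate.** Rank-based AUC (ties 1/2) on training and test scores,
   with 95% percentile confidence intervals from 100 class-stratified
   bootstrap resamples; stratification guarantees both classes in every
   resample. Sensitivity and specificity are reported at the Youden
   threshold (maximising sensitivity + specificity - 1 over observed
   training cut-points, ties to the lower threshold, i.e. higher
   sensitivity), applied unchanged to the test scores.
7. **Compare.** Bootstrap AUC distributions of different time points are
   compared by one-sided Mann-Whitney tests (tie-corrected normal
   approximation without continuity correction, so p(a>b) + p(b>a) = 1).

**Separate vs cumulative analysis.** In separate mode each time point's own
118 features go through steps 2-6. In cumulative mode the design at week w
is the union of the separate-mode pruned selections at CT and weeks 1..w
(prefixed `TP:FEATURE`), so the cumulative column set grows monotonically;
the union is not re-pruned - redundancy control happened per time point,
and the elastic net handles the remaining collinearity.

**Optimal week.** The selected re-planning time point is the earliest t
such that no later time point's training-AUC bootstrap distribution
significantly exceeds t's (one-sided p < 0.05). If nothing ever improves
significantly, CT is returned; a selection on the final treatment week is
annotated "limited practical utility" since no fractions remain to adapt.
The rule is a formalisation of "earliest week after which no significant
improvement occurs" and is exposed through `selectOptimalWeek()` so
alternative rules can be plugged in.

Per-coefficient p-values in the reports come from an unpenalised logistic
refit on the non-zero support (the penalised fit provides no standard
errors); the reports state this.

## The synthetic phantom cohort

No clinical images ship with the package; the generator supplies cohorts
with the statistical structure the analysis assumes:

* **Cohort structure.** Default 59% of patients on 74 Gy/37F and 41% on
  60 Gy/20F; endpoint prevalence 0.33; labels Bernoulli(prevalence).
* **Anatomy.** Per slice, an elliptical rectum (per-patient outer radius
  from `radiusRange`, default 8-14 px on a 64x64 grid, 5 slices) with mild
  per-fraction centre/radius jitter and per-slice radius variation. Soft
  tissue-like intensities: background 0, lumen 20, wall 60 (HU-like).
* **Wall texture.** A spatially correlated Gaussian field (white noise
  smoothed with a Gaussian kernel, correlation length 2 px), standardised
  over the wall band so the realised wall-texture SD equals the design
  value exactly (the smoothed field has few effective degrees of freedom
  within one ring, so its raw variance would fluctuate strongly between
  scans). The design SD is patient-specific:
  `sigmaTexture * exp(N(0, 0.15))` with cohort median `sigmaTexture = 35` -
  lognormal between-patient biological heterogeneity. The two scales are
  deliberate: scan-level standardisation keeps the *modality* and *effect*
  contracts sharp, while the patient-level spread keeps the class overlap
  realistic - with `delta = 1` at half ramp the single-feature separation
  is about Phi(log(1.5) / (2 * 0.15 * sqrt(2))) ~ 0.83 AUC
  (the patient-level nuisance acts on the variance scale, hence the
  factor 2), the regime the
  modelling chain is designed to operate in, rather than a trivially
  perfect separator. The intensity triplet and texture SD were chosen once
  so that the declared effect mechanism - wall-texture variance - is the
  dominant class difference rather than incidental anatomy contrast; with
  a much darker lumen or weaker texture, window variance is dominated by
  tissue-interface contrast and the injected effect is not recoverable at
  the documented power.
* **Effect injection.** For endpoint-positive patients the wall-texture
  variance is multiplied by `1 + delta * ramp(week)` with
  `ramp(w) = min(1, max(0, (w - w0 + 1)/2))`: the effect appears at onset
  week `w0` (default 1), reaches half strength there and saturates one
  week later. The planning CT uses week-0 texture (no effect). Default
  effect size `delta = 1` (a 1x baseline-variance shift at full ramp).
* **Modality.** Additive white acquisition noise, SD 5 on the planning
  image and 15 on daily images, so daily images are reliably noisier.
* **Determinism.** One master seed; per-patient seeds are drawn once from
  it, so cohorts are bit-reproducible and patients are independent.

What the phantom does *not* emulate: real pelvic anatomy (bladder, bone,
gas), intensity calibration differences between kVCT and MVCT, organ
deformation beyond affine jitter, dose-response coupling, or
inter-observer contouring variability. Passing calibration and recovery
tests on phantoms therefore demonstrates that the pipeline is statistically
sound (no label leakage, correct null behaviour, power against its declared
effect mechanism), not that the published clinical effect sizes are
reproduced - the clinical images are not publicly deposited, so clinical
AUCs are out of reach by construction.

## Problem sizes used in the test suite

The packaged tests run the full chain on scaled phantoms - 32x32
single-slice scans, rectum radii 4.5-6.5 px, courses truncated after the
fractions the test needs (e.g. 5 fractions for week-1 properties), n = 120
patients, 20 seeded repeats for the calibration properties - keeping one
end-to-end repeat at roughly 25 s while preserving every structural element
of the analysis (ring, tiling, 118 features, weekly aggregation, split,
screen, prune, 500-point CV grid, 100 bootstrap resamples). Stochastic
properties are asserted with one-sided binomial 95% bounds at the stated
rates (e.g. >= 16/20 at a true rate of 0.90), so a correct implementation
fails such a test with probability below about 3% while a miscalibrated one
is still caught.

## Known limitations

* Slice-wise (2D) analysis only; no volumetric texture and no shape/volume
  features (the ROI is a fixed-width ring by construction).
* No image registration or dose accumulation: features are aggregated per
  scan, not mapped voxel-wise across fractions.
* DICOM input is not supported in this build (no DICOM reader among the
  package's dependencies); NIfTI and a plain-text raw-array JSON container
  are the supported image formats, with contours as JSON polygons.
* The cumulative design depends on the separate-mode selections, so the
  two modes must run in that order (enforced with a clear error).
* Bootstrap confidence intervals are percentile-based; with perfectly
  separated training scores they collapse to [1, 1].
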