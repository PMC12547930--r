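# rectomics

Longitudinal radiomics of the rectal wall for timing adaptive re-planning
in prostate radiotherapy.

Prostate cancer radiotherapy is delivered over 20 or 37 daily fractions with
daily image guidance (MVCT on helical TomoTherapy). Those daily images are
normally used only to position the patient, but they sample the rectal wall
— the organ at risk for late rectal bleeding — at every fraction.
`rectomics` turns that by-product into a decision signal: it extracts
texture features of the rectal wall from the planning CT and every daily
image, aggregates them into weekly time points, models the binary endpoint
*grade ≥ 1 rectal bleeding at two years*, and identifies the earliest
treatment week at which a re-planning decision would be best informed. It is
aimed at radiotherapy physics and outcome-modelling groups working with
serial guidance imaging.

## What it computes

**ROI and subimages.** Per slice, the rectum contour is rasterised
(centre-inclusive rule) and the *rectal wall* is the 2-pixel ring
`mask − erode²(mask)` (3×3 square element). 8×8-pixel subimages are tiled
along the ring at 1-pixel intervals, each window extending 3 pixels beyond
the 2-pixel band (3 + 2 + 3 = 8); border-crossing windows are dropped.

**Features.** Each window yields 118 features (IBSI-style definitions):
23 first-order (FOS), 25 GLCM, 16 GLRLM, 16 GLSZM, 16 GLDZM, 5 NGTDM and
17 NGLDM, computed on fixed-bin-number discretised levels (default
N<sub>g</sub> = 8), with GLCM/GLRLM direction-averaged over 0°/45°/90°/135°.
Vectors are averaged over all windows and slices per scan, then over the
fractions of each treatment week (74 Gy/37F → CT, W1…W7; 60 Gy/20F → CT,
W1…W4).

**Model.** Per regimen and time point: stratified 75:25 split → z-scoring
with training parameters → Mann–Whitney screen → Spearman redundancy pruning
(|ρ| ≥ 0.8 drops the less significant member) → elastic-net logistic
regression (L1 ratio 0.5; C tuned over 500 log-spaced values in
[10⁻⁴, 10³] by 5-fold CV maximising mean fold AUC) → AUC with 95 % CIs from
100 stratified bootstrap resamples, sensitivity/specificity at the Youden
threshold. Time points are analysed *separately* (each week on its own) and
*cumulatively* (the union of the pruned selections from CT up to week w).
Bootstrap AUC distributions are compared with one-sided Mann–Whitney tests;
the **optimal re-planning week** is the earliest time point that no later
time point significantly improves on (p < 0.05).

Because the underlying clinical images (a prospective TomoTherapy cohort)
are not publicly deposited, the package ships a seeded synthetic phantom
generator that reproduces the cohort's statistical structure — regimen mix
59 %/41 %, endpoint prevalence 33 %, an annular wall whose correlated
Gaussian texture gains variance in endpoint-positive patients from a
configurable onset week, and noisier daily images than the planning scan —
so every stage is testable end to end.

## Worked example

A small all-60 Gy phantom cohort (40 patients, fractions 1–10, wall-texture
effect from week 1), simulated, extracted, and modelled in one call:

```r
library(rectomics)

cfg <- pipelineConfig(
  seed = 7, folds = 3, makePlots = FALSE,
  simulate = list(nPatients = 40, regimenMix = 0, shape = c(32L, 32L),
                  nSlices = 1L, radiusRange = c(5, 6.5),
                  delta = 1, onsetWeek = 1, maxFractions = 10))
run <- runPipeline(cfg, outDir = "demo_run")

run$sweeps[["60Gy_20F"]]$separate
#> TimepointSweep (separate mode): CT, W1, W2
#>   CT  train AUC 0.863, test AUC 0.381 (4 features)
#>   W1  train AUC 0.826, test AUC 0.952 (6 features)
#>   W2  train AUC 0.925, test AUC 1.000 (3 features)

run$optimal[["60Gy_20F.separate"]]$timePoint
#> [1] "W2"

round(modelCoefficients(sweepModels(run$sweeps[["60Gy_20F"]]$separate)$W1), 3)
#> (Intercept)     W1:FOS6    W1:FOS21   W1:GLCM10  W1:GLRLM16  W1:GLSZM16
#>      -1.292      -0.197       0.189      -0.077      -0.173      -0.166
#>   W1:NGLDM8
#>      -0.094
```

Reading the output: on the planning CT — acquired before any effect is
injected — the apparent training AUC of 0.86 is overfitting on 30 training
patients, exposed by the test AUC of 0.38; from week 1, the injected
wall-texture variance shift carries real signal (test AUC 0.95), and the
model's features are texture-spread measures (minimum intensity, histogram
gradient level, run-length and zone-size non-uniformity), which is how a
variance effect surfaces after per-window discretisation. The effect ramps
to saturation in week 2 and the week-2 model is significantly better on the
training bootstrap, so the separate-mode optimal time point at this small
demo size is week 2. `demo_run/` contains the scan-level feature tables
(tidy/wide CSV), per-time-point metrics and non-zero coefficients with
refit p-values (CSV/Markdown), and a JSON run manifest (config hash, seed)
that makes the run bit-reproducible.

At this demo size glmnet warns about small per-class fold counts
("fewer than 8 observations"); that is expected and disappears at realistic
cohort sizes.

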