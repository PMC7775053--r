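# qusradiomics

Quantitative ultrasound (QUS) spectral parametric imaging and texture-based
benign/malignant lesion classification, end to end in R — from raw
beamformed RF frames to spectral parameter maps, radiomic texture features,
statistical screening, and cross-validated classifiers, with a seeded RF
speckle simulator supplying ground-truth-known data at every stage.

## Who this is for

Researchers in tissue characterization / quantitative ultrasound who need a
self-contained, testable implementation of the classic QUS radiomics
pipeline: reference-phantom normalization, spectral-difference attenuation
estimation, mid-band-fit / spectral-slope / spectral-intercept regression,
Gaussian-form-factor scatterer estimates, and GLCM / GRLM / GLSZM texture
features over a tumour core and its 5-mm peritumoural margin.

## The model in brief

The backscatter coefficient of a sample window is estimated against a
reference phantom (attenuation 0.786 dB/cm/MHz, sound speed 1540 m/s):

    sigma_m(f) = sigma_r(f) * |S_m|^2 / |S_r|^2 * exp{4 (alpha_m - alpha_r)(R + dz/2)}

with attenuations in Np/cm and the factor 4 for two-way power travel. A
line fit of the dB spectrum over the 3–8 MHz band gives SS (slope), SI
(0-MHz intercept) and MBF = SS·f_c + SI; fitting the spherical Gaussian
form-factor model `sigma = C f^4 a_eff^6 n_z exp(-0.827 k^2 a_eff^2)` gives
the average scatterer diameter (ASD = 2 a_eff) and acoustic concentration
(AAC = 10 log10 n_z). Sliding a 2-mm, 94%-overlap kernel produces five
co-registered parametric maps; 16-level mask-aware texture matrices
(co-occurrence, run-length, size-zone) summarize their heterogeneity; and
forward sequential feature selection (max 10 features, training F1) feeds
LDA / KNN / SVM-RBF / Levenberg–Marquardt ANN classifiers under LOOCV or
repeated stratified 70/30 hold-out.

## Worked example

Round-trip a backscatter curve through the form-factor fit, then rerun the
attenuation-estimation validation study at small scale:

```r
library(qusradiomics)

b <- synthesize_bsc(asd_um = 64, aac_db = 43.5, band = c(3, 8))
fit <- fit_gaussian_form_factor(b)
fit$ASD
#> [1] 64
fit$AAC_dB
#> [1] 43.5

# spectral-difference attenuation estimation on simulated speckle:
# true slope 1.0 dB/cm/MHz vs the 0.786 reference, 8-wavelength window,
# 40-wavelength ROI
errs <- ace_error_experiment(n_realizations = 5, seed = 7)
round(100 * errs, 1)
#> [1] -5.3  3.9 -4.8  1.9 -5.9
```

The five signed relative errors (percent) are each a few percent — the
estimator's rated regime promises mean |error| below 15% and SD below 10%,
and this run shows 4.4% and 4.6%.

Simulating a labelled two-lesion cohort and extracting its 25-column
core-GLCM feature table:

```r
spec <- cohort_spec(n_benign = 1, n_malignant = 1, seed = 5)
cohort <- generate_synthetic_cohort(spec)
ref <- simulate_reference_frames(spec$geometry, seed = 99)
cfg <- sliding_window_config(kernel_mm = 2, overlap = 0.80)

feats <- lapply(cohort, function(les) {
  imgs <- build_parametric_images(les$frames[[1]], ref, cfg, les$contour)
  core <- rasterize_roi(les$contour, imgs$grid)
  margin <- build_margin(core, 5)
  extract_lesion_features(list(imgs), list(core), list(margin), "GLCM")
})
tb <- assemble_feature_table(feats, sapply(cohort, `[[`, "label"),
                             region = "core", method = "GLCM")
ncol(tb) - 1   # 25 features + label
#> [1] 25
```

## Layout

- `R/` — data containers & I/O, ROI geometry, spectral estimation,
  parametric imaging, texture features, screening, classifiers, simulator
- `tests/testthat/` — unit, property and acceptance suites with brute-force
  texture oracles
- `inst/cli/` — `classify.R` and `simulate.R` command-line entry points
- `vignettes/qus-texture-classification.Rmd` — the methods vignette
  (assumptions, conventions, design choices, limitations)
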