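---
title: "Quantitative ultrasound spectral imaging, texture features, and lesion classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QUS texture classification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

B-mode ultrasound appearance is system- and operator-dependent, which limits
quantitative characterization of breast masses. Quantitative ultrasound (QUS)
spectroscopy instead analyses the raw beamformed radiofrequency (RF) echo
signal: after normalization against a well-characterized reference phantom,
the frequency dependence of the backscattered power carries information about
tissue microstructure — the effective size, number density and acoustic
contrast of sub-resolution scatterers. Because benign and malignant lesions
tend to differ not only in their average microstructure but in its *spatial
heterogeneity*, this package pairs QUS parametric imaging with statistical
texture analysis over the tumour core and a 5-mm peritumoural margin, and
feeds the resulting features into screened, cross-validated classifiers.

## From RF data to parametric images

**Windowed spectra.** A square kernel (default 2 mm, 94% overlap between
adjacent positions) slides over the frame. Within each window every scan line
segment is gated with a Hanning taper, zero-padded to at least 4x its length,
Fourier transformed, squared, and the periodograms are averaged across lines.
At a 6.5 MHz center frequency and clinical geometry (512 lines over 6 cm,
40 MHz sampling) the kernel spans 8 acoustic wavelengths axially and 17 scan
lines laterally — enough for usable spectral estimates while preserving image
texture.

**Reference-phantom normalization.** The measured backscatter coefficient is

$$\sigma_m(f) = \sigma_r(f)\,\frac{|S_m(f)|^2}{|S_r(f)|^2}\,
  e^{\,4\,(\alpha_m-\alpha_r)\,(R+\Delta z/2)}$$

with $\sigma_r$ the known reference BSC, $S_m, S_r$ the sample and reference
window spectra, $R$ the distance from the transducer to the proximal window
edge and $\Delta z$ the gate length. Attenuations enter in Np/cm. A
user-facing slope $\beta$ in dB/cm/MHz means one-way *amplitude* attenuation
($\alpha_{np} = 0.11513\,\beta f$); round-trip power then carries
$e^{-4\alpha_{np} z}$, i.e. the received dB power falls by $2\beta f$ per cm
of one-way depth. This single convention is used by the normalization, the
attenuation estimator and the simulator, so the identity closes exactly; note
that mixing amplitude-dB and power-Np bookkeeping would change the spectral
difference slope by a factor 2.

**Attenuation handling.** Intervening breast tissue is assumed to attenuate
at 1 dB/cm/MHz. The tumour's own attenuation (ACE) is estimated once per
frame by the spectral-difference method: for each analysis frequency the
slope of the sample-minus-reference dB power against window depth is
computed over windows marching down the tumour ROI, the per-frequency slopes
are regressed through the origin against frequency (attenuation is assumed
linear in $f$), and $\hat\beta = \beta_r - m/2$. Path corrections below the
proximal tumour depth use the ACE; windows above it use the intervening
assumption. In the estimator's rated regime (window > 5 wavelengths, ROI >
35 wavelengths) the packaged validation study (`ace_error_experiment()`)
measures mean relative errors of a few percent — the acceptance suite checks
the published bounds (mean < 15%, SD < 10%).

**Spectral parameters.** On the analysis band (default 3–8 MHz) an ordinary
least-squares line through the dB BSC gives the spectral slope (SS, dB/MHz),
the 0-MHz intercept (SI, dB), and the mid-band fit MBF = SS·f_c + SI — an
identity maintained at every pixel by construction. A spherical Gaussian
form-factor model

$$\sigma_{theor}(f) = C f^4 a_{eff}^6\, n_z\, e^{-0.827 k^2 a_{eff}^2},
  \qquad C = \pi^2 / (36 c_l^4)$$

is fitted to the measured BSC in dB by grid search over candidate diameters
(ASD = 2a_eff, default grid 10–200 µm in 1 µm steps, covering the dynamic
range of clinical ASD maps); for each candidate the optimal concentration
has the closed form $n_z = 10^{\overline{\Delta dB}/10}$, so the fit is a
1-D deterministic search. AAC is reported as $10\log_{10} n_z$ (relative
units: the absolute scale cancels in the sample/reference ratio, so only
consistency with the reference curve's units matters). The exponent constant
0.827 and the radius convention follow the standard spherical-Gaussian form
factor of the QUS literature; the band-center evaluation of MBF coincides
with the band-mean of the fitted line for the symmetric default band.

## Regions, texture, and the feature inventory

The radiologist-style core contour is rasterized by the pixel-center
even-odd rule (edge ties count as inside); the margin is generated
geometrically as the set of pixels within 5 mm Euclidean distance of the
core (exact distance transform in physical mm, anisotropic pixels
respected), clipped at image bounds and disjoint from the core by
construction.

Each of the five maps is quantized over each region separately into 16 gray
levels spanning that region's own value range (cross-region comparability is
carried by the mean-value and CMR/CMCR features instead). Three matrix
families are computed mask-aware — co-occurring pairs need both pixels in
the region; runs and zones break at region boundaries:

* **GLCM** — symmetric co-occurrence matrices at distances 1–5 pixels and
  angles 0/45/90/135; contrast, correlation, energy, homogeneity; averaged
  over the 20 configurations. Correlation of a constant region is undefined
  and propagates as a missing value.
* **GRLM** — run-length matrices in the four directions; 14 features (SRE …
  RE), averaged over directions. Emphasis/nonuniformity features use raw run
  counts with 1/s (or 1/N for run percentage) prefactors as printed; the
  variance and entropy features are evaluated on the s-normalized matrix so
  the means they reference are proper expectations. 0·log 0 terms are 0.
* **GLSZM** — direction-independent size-zone matrix with 8-connected zones
  (the 2-D literature default; the classic size-zone formulation leaves
  the connectivity unstated); 14 features with the zone count N_Z as
  normalizer.

Per lesion, features are computed per scan plane and averaged across planes
weighted by the plane's core ROI pixel count. The feature inventory is
forced by the design: 5 mean values + 4 texture features x 5 maps = 25 per
region for GLCM (60 with both regions plus 5 CMR + 5 CMCR), and 5 + 14 x 5
= 75 per region for GRLM/GLSZM (160 combined).

## Screening and classification

Each feature is screened for a benign/malignant difference with a
normality-gated test: Shapiro-Wilk at α = 0.05 in *each* group (the
conservative reading of per-feature normality testing); both normal → pooled
two-sided t test, otherwise Mann-Whitney U (exact for groups of ≤ 20 without
ties, normal approximation with tie/continuity correction otherwise). No
multiple-testing correction is applied — screening is descriptive, not
inferential. Tiers: * p<0.05, ** p<0.01, *** p<0.001.

Classification uses forward sequential feature selection maximizing
training-set F1 (malignant positive), capped at 10 features (the 10% rule
of thumb against overfitting); the returned subset is the prefix of the
greedy path with the best F1, earliest size on ties. Candidate ties are
broken by the feature's two-sample t statistic: flexible models (the ANN,
1-NN) interpolate their training set, so many candidates reach F1 = 1 and
the tie-break is what makes selection informative. KNN is always scored on
its training set by leave-one-out voting (excluding each point's self
vote), without which the k = 1 resubstitution F1 is identically 1. Four classifiers are
implemented natively:

* **LDA** — two-class shared-covariance Gaussian discriminant with priors
  from class frequencies; a trace-scaled ridge (1e-6) guards singular pooled
  covariance.
* **KNN** — Euclidean majority vote, k chosen from {1, 3, 5} by training F1
  when not fixed.
* **SVM-RBF** — C-SVC trained by SMO; C and γ tuned by exhaustive grid
  search (C = 2^{-5..15}, γ = 2^{-15..3}, steps of 2 in the exponent —
  the conventional libsvm-style ranges) scored by stratified
  5-fold F1. The grid runs once per training fold on the SFS-selected
  subset; scoring every SFS candidate with the full grid would multiply the
  cost by ~10^2 without changing the selected models in practice.
* **ANN** — one hidden layer of 20 sigmoid units, softmax output, full-batch
  Levenberg-Marquardt on the MSE against one-hot targets (µ starts at
  0.001, x0.1 on improvement, x10 on failure, abort above 1000; max 1000
  epochs; gradient floor 1e-7; stop after 6 consecutive validation
  non-improvements with best-epoch weight restore). Weights initialize
  uniform(-0.5, 0.5) scaled by fan-in, seeded.

Validation is leave-one-out or repeated stratified 70/30 hold-out (10
realizations); standardization, SFS and hyperparameter search are all refit
inside each training fold/split — the defensible reading of "selection on
the training set", avoiding leakage. The ANN carves a validation subset out
of its training portion, reproducing a 70/15/15 overall split. Stratification
stabilizes small-test-set metrics and is recorded as a design choice
(plain unstratified splitting is the obvious alternative). Reports carry sensitivity, specificity,
accuracy, PPV, NPV (percent, malignant positive) and AUC (Mann-Whitney
statistic of the continuous scores, ties at one half).

## The simulator: what it emulates, and what it does not

`simulate_rf_frame()` synthesizes beamformed RF lines in the frequency
domain: scatterers are placed uniformly (Poisson counts) in each line's
lateral strip; each contributes a delayed Gaussian-envelope pulse echo
weighted by a per-scatterer amplitude response $\sqrt{C} f^2 a^3
\sqrt{n_z/\rho}\, e^{-0.827 k^2 a^2 / 2}$, so the ensemble expected power
ratio against a reference built the same way equals the Gaussian-form-factor
BSC ratio exactly (an intentional inverse-crime for unit testing; real
tissue does not follow the fitted model). Frequency-dependent two-way
attenuation is applied per scatterer along its propagation path, including
piecewise paths through a circular lesion. The reference phantom
(0.786 dB/cm/MHz, 1540 m/s) records its BSC curve analytically from the
same forward model, closing the normalization identity.

Within-lesion heterogeneity is a seeded Gaussian random field (spectral
synthesis) added in dB to the local concentration; the two-class cohort
generator gives malignant lesions a shorter correlation length and larger
variance (emulating the clinically reported "less obvious heterogeneity" of
benign masses), with class-conditional means for ASD/AAC/attenuation. The
default class means place AAC near the clinically reported core values
(≈ 47 vs ≈ 43.5 dB) with 1.5 dB within-class spread.

Not modelled: elevational beam width and lateral beam overlap between lines
(each line sums only its own strip, so Rayleigh envelope statistics require
~2000 scatterers/mm² rather than the hundreds a real beam integrates —
spectral-ratio estimators are unbiased at the 200/mm² default), diffraction
and focusing, nonlinear propagation, and transducer element geometry. A
green end-to-end test therefore establishes the correctness of the
estimation pipeline under its own forward model, not clinical performance;
the published clinical accuracies are computed on a 193-patient RF dataset
that is not publicly deposited and are out of scope here.

## Numerical choices and degenerate inputs

* FFT length: next power of two ≥ 4x the gate; periodogram scaling cancels
  in the sample/reference ratio.
* Constant quantization regions map to level 1; GLCM correlation, CMR with a
  zero-spread margin, and CMCR with two zero-spread regions return missing
  values rather than errors, and missing values average away in sweeps
  (all-missing stays missing).
* Population (N-denominator) standard deviations in region summaries and
  CMR/CMCR; N vs N-1 is a pure convention here and the choice is recorded.
* Ties: SFS feature ties resolve to the lowest column index and size ties to
  the smallest subset; grid-search ties to the smallest C then smallest γ;
  the form-factor grid argmin takes the smallest diameter; flat form-factor
  objectives flag `low_confidence` instead of erroring.
* Windows that would exit the frame are dropped (no padding); hold-out
  splits that lose a class are resampled with a shifted seed.
* All indices are 0-based half-open at the RF-sample level, matching the
  on-disk format documentation; R-facing matrices are 1-based as usual.

## Desk scaling in the test suite

The test suite runs the full pipeline at a reduced field of view (13 mm x
16 mm frames, 112 lines at 32 MHz sampling), 0.80 window overlap instead of
the clinical 0.94, cohorts of 20-24 lesions, 4-frame map studies, and 30
realizations of the attenuation-error study (the acceptance script runs the
full 100). These reduce runtime, not fidelity: every estimator operates at
the same wavelengths-per-window and lines-per-kernel regime as the clinical
configuration.
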