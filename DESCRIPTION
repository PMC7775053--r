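Package: qusradiomics
Title: Quantitative Ultrasound Spectral Parametric Imaging and Texture-Based
    Lesion Classification
Version: 0.1.0
Authors@R: person("QUS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for characterizing breast lesions from raw
    beamformed radiofrequency (RF) ultrasound data. Computes reference-phantom
    normalized backscatter coefficients, spectral-difference attenuation
    estimates, and sliding-window parametric images of mid-band fit, spectral
    slope, spectral intercept, average scatterer diameter, and average
    acoustic concentration. Extracts gray-level co-occurrence, run-length, and
    size-zone texture features over tumour core and a 5-mm peritumoural
    margin, screens features for benign-versus-malignant differences, and
    classifies lesions with forward sequential feature selection and LDA,
    k-nearest-neighbour, RBF-kernel support vector machine, or shallow neural
    network classifiers under leave-one-out and repeated hold-out validation.
    Includes a seeded point-scatterer RF speckle simulator and synthetic
    cohort generator for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
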