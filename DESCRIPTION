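Package: fluorograde
Title: Multiscale Autofluorescence Analysis for Grading Meningeal Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate meningioma grades from non-tumoral brain
    tissue using label-free autofluorescence measurements across excitation
    scales, from deep-ultraviolet micro-spectroscopy to near-infrared
    two-photon imaging. Implements constrained Gaussian spectral unmixing of
    emission spectra into endogenous fluorophore contributions (tyrosine,
    tryptophan, collagen crosslinks, NADH, FAD, lipopigments, porphyrins,
    second-harmonic generation), molecular and metabolic ratios, spectral
    phasor analysis of hyperspectral image cubes, fluorescence-lifetime (FLIM)
    phasor analysis with universal-circle lifetime extraction and
    long-lifetime intensity fraction histograms, Poisson-weighted
    bi-exponential decay fitting, and a three-dimensional Gaussian-ellipsoid
    classifier over collagen-derived features with threshold-rule diagnosis.
    A seeded synthetic-data generator emulates per-grade spectra, hyperspectral
    cubes and photon-counting decay cubes so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
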