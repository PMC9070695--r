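Package: streakless
Title: Ring Artifact and Poisson Noise Attenuation for Volumetric Tomography
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage, fully automatic sinogram-domain denoising of volumetric
    tomography projections. Stage one attenuates streak noise (the precursor of
    ring artifacts in reconstructed tomograms), modeled as angularly constant,
    long-range-correlated stationary noise, through a coarse-to-fine multiscale
    binning pyramid with self-calibrated, segment-adaptive power spectral
    densities. Stage two attenuates the Poissonian noise component through an
    adaptive data-driven variance-stabilizing transform and multiscale
    volumetric filtering. Both stages are driven by a PSD-aware volumetric
    collaborative filter (BM4D-style block matching, 4-D transform shrinkage
    with per-coefficient noise variances derived from an arbitrary 3-D PSD,
    hard-threshold and Wiener stages, weighted aggregation). Includes a
    synthetic phantom projection generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
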