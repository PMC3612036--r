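Package: vmhc
Title: Voxel-Mirrored Homotopic Connectivity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of interhemispheric resting-state functional
    connectivity using voxel-mirrored homotopic connectivity (VMHC): BOLD
    preprocessing (volume discard, Gaussian smoothing, nuisance regression,
    ideal band-pass filtering), framewise-displacement motion QC, symmetric
    template and unilateral gray-matter mask construction, per-subject Fisher-z
    homotopic correlation maps, covariate-adjusted voxel-wise group statistics
    and clinical correlations, AlphaSim-style Monte-Carlo cluster-extent
    correction, and a gray-matter ROI confound check. Includes a seeded
    synthetic-cohort generator with known homotopic-correlation ground truth
    for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
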