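Package: datspect
Title: Semi-Quantitative Analysis of Dopamine Transporter SPECT with
    Multi-Template Stereotactical Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic semi-quantitative analysis of dopamine transporter
    (DAT) SPECT images. Provides affine stereotactical normalization of
    native scans to template space against a single template or the best
    linear combination of multiple templates representative of normal and
    Parkinson-typical reduction of striatal uptake, iterative template
    construction, intensity scaling to distribution volume ratio (DVR)
    images, putamen specific binding ratio (SBR) extraction by
    hottest-voxels and anatomical region-of-interest analysis, and
    cohort-level statistics (two-Gaussian histogram modelling with effect
    size and cutoff, subsample stability, agreement cross-tables with
    Cohen's kappa, SBR-DET regressions). Includes a digital phantom
    simulator of DAT-SPECT cohorts with ground-truth transforms and SBR,
    and minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
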