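Package: isokin
Title: Amino Acid Turnover Kinetics from 15N Stable Isotope Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 15N metabolic labeling time courses for free amino
    acids measured by LC-MS. Extracts per-isotopologue ion chromatograms from
    mzML files, computes the unlabeled (M0) fraction of each isotopic
    envelope, fits the plateau-exponential decay model
    M0(t) = (1 - c) exp(-k t) + c by bounded nonlinear least squares, and
    derives pool sizes against a labeled internal standard, active pools,
    and turnover-adjusted (flux-dimension) pool sizes. Includes k-means
    clustering of labeling trajectories with Hartigan-Wong updates,
    F-test-gated pairwise t-tests across growth conditions, and a synthetic
    data generator that emulates the full experiment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    mzR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
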