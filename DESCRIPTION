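Package: erkrescale
Title: Calibrated Single-Cell ERK Activity Analysis for RAS Isoform Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of ERK signaling downstream of single RAS
    isoforms measured with a FRET kinase reporter. Implements the ratiometric
    reporter correction and mass-action calibration that converts corrected
    FRET signal to the ERK:phosphatase activity ratio; per-cell time-series
    descriptors (baseline, peak, amplitude, steady state, volatility,
    responder classification, time to peak) with MEK-inhibitor reference
    normalization and quality control; a steady-state model of the internal
    RAS-RAF-MEK-ERK cascade that predicts phosphorylated ERK per RAS isoform
    from GTPase-cycle kinetics and protein abundances; phosphatase-activity
    inference from ppERK/activity ratios and single-cell exponential decay
    after MEK inhibition; and the accompanying statistics (two-level-error
    t-tests with Benjamini-Hochberg FDR, partial least squares regression with
    permutation-null significance bounds, Tjur's coefficient of
    discrimination). A synthetic-data generator with known ground truth makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mixOmics
Config/testthat/edition: 3
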