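Package: mpri
Title: Semi-Quantitative Myocardial Perfusion Reserve Analysis for First-Pass Cardiac MR
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative analysis of first-pass myocardial
    perfusion imaging: segmental time-intensity curve extraction, baseline and
    contrast-arrival detection, sliding-window maximum up-slope estimation,
    left-ventricular cavity normalization, and myocardial perfusion reserve
    index (MPRi) computation from rest, vasodilator stress, and recovery
    acquisitions. Includes a tracer-kinetic digital phantom (gamma-variate
    arterial input, one-compartment myocardial kinetics) with known ground
    truth for validating the pipeline, delayed-hyperemia classification,
    cohort summary tables, Welch and paired t-tests, Fisher's exact test,
    two-group sample-size calculation, and a reproducible file-based pipeline
    (NIfTI image series and masks, CSV curves, YAML configuration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
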