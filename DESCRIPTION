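Package: stabmeth
Title: Stability-Selected Gradient Boosting for Blood DNA Methylation
    Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and evaluation of peripheral-blood DNA methylation
    biomarkers of treatment response from Illumina-style beta-value
    matrices. Implements composite clinical/biochemical/endoscopic response
    endpoints, gap-signal probe filtering, stability-selected gradient
    boosting with a permutation shadow-variable selection threshold,
    recalibrated ensemble evaluation with mean ROC curves and likelihood
    ratios, longitudinal biomarker stability via intraclass correlation
    with Koo-Li interpretation bands, reference-based blood cell-type
    deconvolution by constrained least squares, per-probe covariate
    regressions and hypergeometric gene-set over-representation. Ships a
    synthetic-data generator emulating the statistical structure of a small
    two-arm longitudinal methylation cohort so the full pipeline is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    quadprog,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
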