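Package: varpcr
Title: qPCR Standard Curves, Detection Limits, and Variance-Based
    Absolute Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting and validating quantitative PCR (qPCR)
    standard curves and for absolute quantification of target copy
    number.  Implements ordinary least-squares calibration of Cq against
    log10 starting copies with efficiency estimation and confidence
    intervals, Working-Hotelling simultaneous bands, standardized
    residual and Grubbs outlier screening, and polynomial lack-of-fit
    tests of the linear dynamic range.  Models Poisson aliquoting
    uncertainty to derive theoretical limits of detection and
    quantification, estimates empirical limits from replicate data, and
    performs inverse prediction of test-sample concentrations with
    standard errors and asymmetric linear-scale confidence intervals.
    Includes varPCR, an estimator of the absolute expected copy number
    per reaction obtained by inverting the theoretical relationship
    between replicate Cq variance and copy number, and a seeded Monte
    Carlo simulator of replicate-level dilution series.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
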