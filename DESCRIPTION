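Package: chemocal
Title: Multivariate Calibration Workflows for Spectrally Overlapped Analytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simultaneous UV-spectrophotometric quantification of
    two spectrally overlapped analytes (cefepime and tazobactam) by
    multivariate calibration. Provides a Beer-Lambert synthetic-spectra
    generator with plasma matrix effects, Brereton multilevel calibration
    designs, D-optimal validation-set selection by Fedorov exchange,
    principal component regression, firefly-optimized partial least squares,
    constrained multivariate curve resolution by alternating least squares
    with evolving factor analysis rank estimation, a full validation
    statistics suite (error metrics, net analyte signal figures of merit,
    elliptical joint confidence regions, matrix factors, recovery tests),
    and per-sample sustainability calculators (carbon footprint, whiteness
    aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
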