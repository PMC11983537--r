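Package: mrpath
Title: Two-Sample Mendelian Randomization and Two-Step Mediation over GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    and two-step MR mediation analysis over GWAS summary statistics.
    Implements instrument selection (significance, minor-allele-frequency,
    LD clumping, outcome-association and instrument-strength filters),
    allele harmonization with palindromic-variant handling, the
    inverse-variance-weighted, MR-Egger and weighted-median estimators with
    Cochran's Q, leave-one-out and MR-PRESSO diagnostics, multivariable MR
    for direct effects, and product-of-coefficients mediation with
    delta-method standard errors and bootstrap confidence intervals for the
    proportion mediated. A summary-statistic-level simulator with
    configurable pleiotropy supports calibration and parameter-recovery
    testing without any external data download.
License: MIT
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
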