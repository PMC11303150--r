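Package: targetmr
Title: Drug-Target Mendelian Randomization with Colocalization and Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of lipid traits
    and lipid-modifying drug-target gene regions against a binary disease
    outcome. Implements cis-instrument selection (significance and
    minor-allele-frequency filters, greedy LD clumping, gene-window
    restriction, instrument-strength statistics), allele harmonization with
    palindromic-variant handling, the random-effects inverse-variance-weighted
    estimator alongside MR-Egger, weighted-median and mode-based estimators,
    multivariable IVW, heterogeneity and pleiotropy diagnostics including a
    simulation-based residual outlier test, Bayesian colocalization via
    approximate Bayes factors, two-step mediation arithmetic with delta-method
    uncertainty, Benjamini-Hochberg false-discovery-rate correction, and a
    synthetic GWAS summary-statistics generator with known ground truth for
    end-to-end validation. All user-facing functions take data frames and
    return tibbles; fitted objects provide tidy() and glance() methods and
    ggplot2 visualizations.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
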