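Package: mrmediate
Title: Two-Step Multivariable Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) estimators and a
    two-step mediation calculus for GWAS summary statistics. Implements
    the inverse-variance-weighted estimator, MR-Egger regression, simple
    and weighted median estimators, single-SNP and leave-one-out
    diagnostics, the MR-PRESSO global, outlier and distortion tests, and
    regression-based multivariable MR. Mediation analysis combines a
    step-1 exposure-to-mediator effect with a step-2 adjusted
    mediator-to-outcome effect by the product method, with delta-method
    standard errors for products, quotients and differences, and a
    difference-method combined mediation summary. Includes allele
    harmonization for two-sample designs, instrument selection
    (genome-wide significance, greedy LD clumping, F-statistics), a
    simulator of summary statistics under an explicit
    exposure-mediator-outcome structural model, and a pipeline
    orchestrating the full two-step workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
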