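Package: mrmediate
Title: Two-Sample Mendelian Randomisation with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) from GWAS
    summary statistics: instrument selection (genome-wide significance,
    greedy LD clumping, F-statistic filtering), allele harmonisation,
    univariable causal estimators (inverse-variance weighted, MR-Egger,
    weighted median), heterogeneity and pleiotropy diagnostics (Cochran's Q,
    Egger intercept, leave-one-out, MR-PRESSO), multivariable MR, and
    two-step MR mediation with product-of-coefficients indirect effects,
    delta-method confidence intervals and signed proportion mediated.
    Includes a generator of synthetic three-trait GWAS summary statistics
    under a linear structural mediation model with known truth, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
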