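Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening with GWAS Summary
    Statistics
Version: 1.0.0
Authors@R:
    person("mrscreen", "developers", email = "mrscreen@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) pipeline for
    screening many exposures against a single outcome using GWAS summary
    statistics: instrument selection (p-value thresholding, greedy LD
    clumping, F-statistic weak-instrument filtering, confounder-SNP
    exclusion), exposure/outcome allele harmonization with palindromic-SNP
    handling, causal-effect estimation by random-effects inverse-variance
    weighting, weighted median, and MR-Egger regression, a sensitivity
    battery (Cochran's Q, MR-Egger intercept, leave-one-out, funnel data),
    and an evidence-classification rule combining significance and
    direction concordance across methods.  Includes a synthetic
    summary-statistics generator with known causal effect and controllable
    horizontal pleiotropy so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
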