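Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    between binary traits from GWAS summary statistics. Covers instrument
    selection at genome-wide significance, greedy LD clumping, allele
    harmonization with palindromic-variant handling, and five causal
    estimators (inverse-variance weighted with multiplicative random
    effects, MR-Egger, weighted median, MR-PRESSO outlier correction, and
    the contamination mixture model), together with Cochran's Q
    heterogeneity, instrument-strength F statistics, analytic power for
    binary outcomes, and a fully seeded synthetic two-sample GWAS generator
    so every stage can be validated against known truth without external
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
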