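Package: mrflow
Title: Two-Sample and Multivariable Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating per-variant association tables, allele
    harmonization across studies, instrument selection by genome-wide
    significance and greedy LD clumping, instrument-strength diagnostics
    (per-SNP F statistics and variance explained), univariable estimators
    (Wald ratio, fixed- and random-effects inverse-variance weighted, MR-Egger,
    simple and weighted median), heterogeneity and pleiotropy diagnostics
    (Cochran Q, Egger intercept, leave-one-out, MR-PRESSO), multivariable MR
    (IVW, Egger, and lasso-based invalid-instrument selection), a synthetic
    summary-statistics generator with attached ground truth for validation,
    and a config-driven pipeline that writes table- and plot-shaped outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
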