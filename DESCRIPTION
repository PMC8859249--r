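Package: mrtwosample
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument construction (genome-wide significance,
    minor-allele-frequency and palindromic-SNP quality control, greedy LD
    clumping, confounder-association exclusion), exposure/outcome allele
    harmonization, a battery of causal-effect estimators (fixed- and
    multiplicative-random-effect inverse-variance weighting with penalized
    and robust variants, maximum likelihood, simple and weighted medians,
    MR-Egger regression), pleiotropy and heterogeneity diagnostics
    (Cochran's Q, Egger intercept test, MR-PRESSO global/outlier/distortion
    tests, leave-one-out series, funnel data), multivariable MR, analytical
    power for binary outcomes, and a seeded synthetic summary-statistics
    generator so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
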