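Package: metabomr
Title: Two-Sample Mendelian Randomization Screening of Serum Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization screens
    of many exposures (serum metabolites) against binary outcomes such as
    sepsis and short-term sepsis mortality, using GWAS summary statistics
    only. Covers instrument selection (p-value threshold, greedy LD clumping,
    per-variant variance explained and F-statistic filtering), effect-allele
    harmonization with explicit palindromic-variant policies, the
    inverse-variance-weighted, MR-Egger, weighted-median and MR-PRESSO
    estimators, heterogeneity and pleiotropy diagnostics (Cochran's Q,
    Egger intercept, PRESSO global test), multi-criterion candidate
    screening with Bonferroni correction and reverse-MR confirmation,
    hypergeometric metabolite-set over-representation analysis, and a
    seeded synthetic summary-statistics generator with known causal truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
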