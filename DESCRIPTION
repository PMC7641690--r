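Package: ironmr
Title: Two-Sample Mendelian Randomization of Iron Status and Vascular Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization (MR) of
    genetically predicted iron status (serum iron, ferritin, transferrin,
    transferrin saturation; three-SNP instrument) against vascular disease
    outcomes, with sex-stratified subgroups. Provides GWAS summary-statistic
    readers with allele harmonization (including palindromic-SNP resolution by
    effect-allele frequency), Wald-ratio estimates with delta-method standard
    errors, fixed-effect inverse-variance weighted pooling, simple and weighted
    median estimators with parametric-bootstrap standard errors, MR-Egger
    regression for directional pleiotropy, a Bonferroni-corrected
    exposure-by-outcome analysis grid with a significant/potential/null
    taxonomy, and a summary-level synthetic-data generator with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
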