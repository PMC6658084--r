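Package: stagegs
Title: Stage-Wise Pedigree and Genomic BLUP for Clonal Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pedigree-BLUP and genomic-BLUP (GBLUP) analysis of multi-stage,
    multi-location clonal breeding trials, as used in cassava selection
    programs. Provides marker quality control and heterozygote imputation,
    pedigree (A) and VanRaden genomic (G) relationship matrices with
    per-location block-diagonal expansions for genotype-by-location effects,
    average-information REML estimation of variance components, Henderson's
    mixed-model equations, likelihood-ratio tests, ten-fold clone-level
    cross-validation (predictive ability, accuracy, bias), SNP-effect
    backsolving, an empirical selection index with genetic-gain estimates,
    and a synthetic biparental-cross trial generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
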