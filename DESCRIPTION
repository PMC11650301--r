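Package: omixwas
Title: Imputation-Based Proteome- and Transcriptome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for imputation-based proteome-wide (PWAS) and
    transcriptome-wide (TWAS) association studies of quantitative traits.
    Trains sparse elastic-net cis-genetic prediction models of residualized
    protein or expression levels, tests gene-trait associations using only
    GWAS summary statistics plus a linkage-disequilibrium reference,
    colocalizes gene and trait signals with approximate Bayes factors, and
    quantifies PWAS-TWAS direction concordance across tissues. Includes the
    omics quality-control pipeline (minor-allele-frequency and relatedness
    filters, rank-based inverse normalization, principal-component and
    surrogate-value outlier screening, covariate residualization) and a
    synthetic-cohort generator with known cis-architecture so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
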