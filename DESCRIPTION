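Package: cgassoc
Title: Candidate-Gene Case-Control SNP Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for candidate-gene case-control
    association studies of biallelic SNPs. Provides genotype and phenotype
    readers (VCF and delimited tables), variant- and sample-level quality
    control with chi-squared and exact Hardy-Weinberg tests, single-SNP
    logistic association under five inheritance models with AIC-based model
    selection, covariate-adjusted likelihood-ratio p-values and permutation
    tests, pairwise linkage disequilibrium and EM haplotype-frequency
    estimation from unphased genotypes, exhaustive best-subset multivariate
    model search with aliasing detection and stepwise gene-environment
    interaction modelling, and ROC-based comparison of risk-prediction
    models (bootstrap AUC intervals, DeLong tests, optimal thresholds).
    A synthetic-cohort simulator reproduces the statistical structure such
    studies assume so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
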