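Package: secretomics
Title: Quantitative Secretome Analysis and Adipokine Candidate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for label-free mass-spectrometry
    secretome analysis: parsing of MaxQuant-style protein-groups tables with
    contaminant/reverse-hit exclusion, detection filtering, left-shifted
    Gaussian imputation of missing-not-at-random intensities, permutation-FDR
    one-way ANOVA across cell types, complete-linkage cluster profiling and
    iBAQ abundance ranking, rule-based secretion-route classification from
    predictor score tables, a percentage tissue-enrichment score computed
    against an expression atlas with empirical-Bayes moderated pairwise tests,
    and the three-criterion intersection (conditioned-medium detection,
    adipose enrichment score, serum detection) that nominates candidate
    adipokines. A synthetic-data module generates every input with known
    ground truth so each stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
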