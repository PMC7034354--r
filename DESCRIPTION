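Package: pregbiome
Title: Longitudinal Cytokine and Gut Microbiome Analysis for Pregnancy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for longitudinal serum-cytokine and
    faecal 16S microbiome cohorts sampled across pregnancy, with inflammatory
    bowel disease (IBD) cohorts in mind. Provides genus-level merging,
    pseudo-count log transformation, statistical whitening and per-timepoint
    detrending of feature tables; Faith's phylogenetic diversity, Shannon and
    Pielou alpha diversity, weighted and unweighted UniFrac with PERMANOVA;
    a two-stage Kruskal-Wallis / linear-discriminant effect-size screen for
    differentially abundant taxa; leave-one-out cross-validated linear
    support-vector classification with ROC/AUC; the full nonparametric
    cytokine-panel test battery (paired Wilcoxon, Friedman with Dunn post hoc,
    Mann-Whitney, Shapiro-Wilk screening, SVD-with-imputation PCA with
    prediction ellipses); and a dynamic cytokine-microbiome correlation
    network in which current levels are correlated with subsequent changes and
    significance is calibrated against a scrambled-bacteria permutation null.
    A seeded synthetic-cohort generator emulates the study design so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
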