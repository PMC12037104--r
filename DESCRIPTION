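Package: metadrift
Title: Concept Drift Detection and Confounder Correction for Metabolomic
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated workflow for improving phenotype classifiers
    built on metabolite abundance tables. Harmonizes datasets to shared KEGG
    compound identifiers with half-minimum imputation and two-standard-
    deviation outlier screening, applies the standard family of metabolomics
    scaling transforms (centering, autoscaling, pareto, range, vast, level,
    log and power), trains and evaluates a suite of reference classifiers,
    monitors their ordered misclassification streams with the DDM and EDDM
    concept drift detectors, associates warning and drift positions with
    clinical covariates to nominate confounding factors and a candidate
    threshold, and corrects the models either by segmenting the cohort at
    the threshold or by fitting scaling parameters within confounder strata.
    A cohort simulator generates synthetic data with covariate-dependent
    concept drift so every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
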