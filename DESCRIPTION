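Package: rarepool
Title: Pooled-Sequencing Rare-Variant Discovery, Functional Classification
    and Carrier Growth-Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for detecting rare
    heterozygous variants from pooled DNA sequencing, recalibrating the
    variant-allele-fraction cutoff against validation labels (ROC/AUC),
    resolving validated calls to individual carriers with cohort exclusion
    rules and exact binomial prevalence estimates, classifying receptor
    variants from dose-response assays (Emax/EC50 logistic fits with
    extra-sum-of-squares F-tests), and quantifying carrier effects on growth
    trajectories with linear-spline two-level mixed models and a polygenic
    score comparison. A synthetic birth-cohort generator reproduces the
    statistical structure of pooled sequencing (beta-binomial overdispersion,
    unequal sample contribution) and longitudinal anthropometry so the whole
    pipeline runs without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    lme4,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
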