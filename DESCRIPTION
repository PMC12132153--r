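Package: isomiRSurv
Title: IsomiR-Based Survival Prognostication for ALS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, isomiR calling, preprocessing, and survival analysis
    machinery for cell-free small-RNA prognostic biomarker studies in
    amyotrophic lateral sclerosis (ALS). Provides a synthetic two-cohort
    generator (negative-binomial UMI counts with batch structure,
    missingness, and planted proportional-hazards effects), a contract-level
    isomiR caller (quality/ambiguity/adapter trimming, reference alignment
    with uniform tie splitting, UMI collapsing, canonical nomenclature),
    a count preprocessing pipeline (abundance filtering, imputation,
    median-of-ratios size normalization, zero restoration, empirical-Bayes
    batch adjustment, cross-cohort standardization), survival statistics
    (Kaplan-Meier, log-rank, Cox proportional hazards with Breslow ties,
    BH-FDR, IPCW time-dependent AUC, cutpoint optimization), a
    bootstrap-subset sequential-forward-selection ensemble for biomarker
    panel discovery, and Shapley-value model explanation with
    attribution-derived hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    withr,
    Biostrings,
    S4Vectors,
    sva,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
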