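#!/usr/bin/env Rscript
# Stage 3: count preprocessing.
#
# Applies, per cohort, the fixed chain: abundance filter (mean > 5 UMIs),
# imputation (deterministic median imputer here; the denoising-autoencoder
# imputer is available through impute_params("dae")), median-of-ratios size
# normalization, restoration of original zeros, and empirical-Bayes batch
# adjustment; then intersects the cohorts' features and standardizes each
# cohort, storing the pre-standardization medians used later for
# dichotomization-threshold transfer.

suppressMessages(library(isomiRSurv))

prep <- list()
for (co in c("discovery", "replication")) {
  counts <- read_counts_tsv(sprintf("results/data/%s_counts.tsv", co))
  clinical <- read_survival_tsv(sprintf("results/data/%s_clinical.tsv", co))
  before <- ncol(counts$values)
  prep[[co]] <- preprocess_cohort(counts, clinical,
                                  params = impute_params("median"))
  cat(sprintf("%s: %d -> %d features after abundance filter; state %s\n",
              co, before, ncol(prep[[co]]$values), prep[[co]]$state))
}

std <- intersect_and_standardize(prep$discovery, prep$replication)
cat(sprintf("shared features after intersection: %d\n",
            ncol(std[[1]]$values)))
write_counts_tsv(std[[1]], "results/discovery_standardized.tsv")
write_counts_tsv(std[[2]], "results/replication_standardized.tsv")
write_counts_tsv(prep$discovery, "results/discovery_preprocessed.tsv")
write_counts_tsv(prep$replication, "results/replication_preprocessed.tsv")
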