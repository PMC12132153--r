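#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces (a) a miRBase-style reference panel plus a small raw-read FASTQ
# with known ground truth, exercising the read-level pipeline, and (b) a
# two-cohort isomiR count + survival dataset at desk scale (120 features;
# cohort sizes, censoring, batch structure and the planted marker follow
# the package's discovery/replication presets).

suppressMessages(library(isomiRSurv))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

seed <- 20260927
n_features <- 120

panel <- make_reference(15, seed = seed)
write_reference_fasta(panel, "results/data/reference.fasta")

profile <- c("isomiR-letA-5p" = 40, "isomiR-letA-5p.t" = 30,
             "isomiR-letB-5p" = 20, "isomiR-mir1-5p" = 15,
             "isomiR-mir2-3p.a" = 10, "isomiR-mir3-5p.tt" = 5)
names(profile)[4:6] <- paste0("isomiR-", panel$gene_id[4:6], "-",
                              panel$arm[4:6], c("", ".a", ".tt"))
reads <- simulate_reads(panel, profile, n_reads = 3000, seed = seed + 1)
write_fastq(reads$reads, "results/data/sample01.fastq")
write_ground_truth_json(reads$truth, "results/data/sample01_truth.json")

cfg_d <- discovery_config(n_features = n_features, seed = seed + 2)
cfg_r <- replication_config(n_features = n_features, seed = seed + 3)
write_config_yaml(cfg_d, "results/data/config_discovery.yaml")
write_config_yaml(cfg_r, "results/data/config_replication.yaml")

sim <- simulate_cohorts(cfg_d, cfg_r)
for (co in c("discovery", "replication")) {
  write_counts_tsv(sim[[co]]$counts,
                   sprintf("results/data/%s_counts.tsv", co))
  write_survival_tsv(sim[[co]]$clinical,
                     sprintf("results/data/%s_clinical.tsv", co))
}
data.table::fwrite(sim$catalog, "results/data/feature_catalog.tsv",
                   sep = "\t")

cat(sprintf("reference panel: %d mature sequences\n", nrow(panel)))
cat(sprintf("reads: %d (ground truth stored)\n", nrow(reads$reads)))
cat(sprintf("discovery: %d patients, %.1f%% censored\n",
            nrow(sim$discovery$clinical),
            100 * mean(1 - sim$discovery$clinical$event)))
cat(sprintf("replication: %d patients, %.1f%% censored\n",
            nrow(sim$replication$clinical),
            100 * mean(1 - sim$replication$clinical$event)))
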