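#!/usr/bin/env Rscript
# Stage 6: panel model, frozen replication evaluation, and explanation.
#
# Fits a Cox model on the selected discovery-panel isomiRs, evaluates the
# frozen risk score on the held-out replication cohort (C-index and IPCW
# mean AUC(t)), computes exact Shapley attributions of the linear risk in
# both cohorts, derives attribution-based hazard ratios, and evaluates the
# top-marker / NfL ratio biomarker with a discovery-optimized cutpoint
# transferred to replication.

suppressMessages(library(isomiRSurv))

sel <- jsonlite::read_json("results/selection_report.json",
                           simplifyVector = TRUE)
panel <- sel$final_panel
if (!length(panel)) stop("stage 5 selected an empty panel; nothing to model")

std_d <- read_counts_tsv("results/discovery_standardized.tsv")
std_r <- read_counts_tsv("results/replication_standardized.tsv")
cl_d <- read_survival_tsv("results/data/discovery_clinical.tsv")
cl_r <- read_survival_tsv("results/data/replication_clinical.tsv")

Xd <- std_d$values[, panel, drop = FALSE]
Xr <- std_r$values[, panel, drop = FALSE]
model <- cox_fit(Xd, cl_d$time, cl_d$event)
print(model)

risk_r <- as.vector(Xr %*% model$table$beta)
auc <- cumulative_dynamic_auc(risk_r, cl_r$time, cl_r$event)
ci <- cindex(risk_r, cl_r$time, cl_r$event)
cat(sprintf("replication: C-index %.3f, mean AUC(t) %.3f over %d event times\n",
            ci, auc$mean_auc, length(auc$times)))

shap <- lapply(list(discovery = Xd, replication = Xr), function(X) {
  at <- shapley_attributions(model, X, "exact")
  list(hr = shap_to_hr(at, X), importance = importance_rank(at))
})
hr_tab <- merge(shap$discovery$hr[, c("feature", "hr_shap")],
                shap$replication$hr[, c("feature", "hr_shap")],
                by = "feature", suffixes = c("_disc", "_repl"))
data.table::fwrite(hr_tab, "results/shap_hazard_ratios.tsv", sep = "\t")
cat("attribution-derived hazard ratios (discovery vs replication):\n")
print(hr_tab, digits = 3)

# ratio biomarker: top univariate marker over NfL
top <- jsonlite::read_json("results/top_marker_km.json")$top_marker
raw_d <- read_counts_tsv("results/data/discovery_counts.tsv")$values[, top]
raw_r <- read_counts_tsv("results/data/replication_counts.tsv")$values[, top]
raw_d[is.na(raw_d)] <- 0; raw_r[is.na(raw_r)] <- 0
ratio_d <- ratio_biomarker(raw_d, cl_d$nfl)
ratio_r <- ratio_biomarker(raw_r, cl_r$nfl)
rule <- optimize_cutpoint(ratio_d, cl_d$time, cl_d$event)
lr_d <- logrank_test(cl_d$time, cl_d$event, dichotomize(ratio_d, rule)$high)
grp_r <- dichotomize(ratio_r, rule)$high
lr_r <- if (length(unique(grp_r)) == 2)
  logrank_test(cl_r$time, cl_r$event, grp_r) else NULL
cat(sprintf("%s/NfL ratio cutpoint %.3g: discovery chi2 %.2f (p %.2g)%s\n",
            top, rule$threshold, lr_d$chisq, lr_d$p,
            if (is.null(lr_r)) "" else
              sprintf(", replication chi2 %.2f (p %.2g)", lr_r$chisq, lr_r$p)))

jsonlite::write_json(list(
  panel = panel, replication_cindex = ci, mean_auc = auc$mean_auc,
  auc_times = auc$times, auc = auc$auc,
  ratio = list(marker = top, threshold = rule$threshold,
               discovery = list(chisq = lr_d$chisq, p = lr_d$p),
               replication = if (is.null(lr_r)) NULL else
                 list(chisq = lr_r$chisq, p = lr_r$p))),
  "results/model_evaluation.json", auto_unbox = TRUE, null = "null",
  digits = NA)
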