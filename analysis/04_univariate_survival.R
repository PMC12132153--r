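#!/usr/bin/env Rscript
# Stage 4: univariate survival screen with replication.
#
# Dichotomizes every shared isomiR at its discovery-cohort median, fits a
# univariate Cox model per isomiR (Breslow ties), adjusts discovery
# p-values by BH-FDR, then transfers the discovery thresholds unchanged to
# the replication cohort and re-tests. The top marker gets Kaplan-Meier /
# log-rank summaries in both cohorts.

suppressMessages(library(isomiRSurv))

scan <- function(m, clinical, rules = NULL) {
  v <- m$values
  res <- data.frame(feature = colnames(v), beta = NA_real_, hr = NA_real_,
                    p = NA_real_, threshold = NA_real_)
  out_rules <- list()
  for (j in seq_len(ncol(v))) {
    d <- tryCatch({
      if (is.null(rules)) dichotomize(v[, j])
      else dichotomize(v[, j], rules[[colnames(v)[j]]])
    }, error = function(e) NULL)
    if (is.null(d) || length(unique(d$high)) < 2) next
    out_rules[[colnames(v)[j]]] <- d$rule
    f <- tryCatch(cox_fit(data.frame(high = d$high), clinical$time,
                          clinical$event),
                  error = function(e) NULL)
    if (is.null(f)) next
    res[j, c("beta", "hr", "p")] <- f$table[, c("beta", "hr", "p")]
    res$threshold[j] <- d$rule$threshold
  }
  list(table = res, rules = out_rules)
}

disc_m <- read_counts_tsv("results/discovery_preprocessed.tsv")
repl_m <- read_counts_tsv("results/replication_preprocessed.tsv")
shared <- intersect(colnames(disc_m$values), colnames(repl_m$values))
disc_m$values <- disc_m$values[, shared]
repl_m$values <- repl_m$values[, shared]
disc_cl <- read_survival_tsv("results/data/discovery_clinical.tsv")
repl_cl <- read_survival_tsv("results/data/replication_clinical.tsv")

disc <- scan(disc_m, disc_cl)
disc$table$q <- bh_fdr(disc$table$p)
repl <- scan(repl_m, repl_cl, rules = disc$rules)

volcano <- merge(disc$table, repl$table, by = "feature",
                 suffixes = c("_disc", "_repl"))
data.table::fwrite(volcano[order(volcano$q), ],
                   "results/univariate_volcano.tsv", sep = "\t")

sig <- !is.na(volcano$q) & volcano$q <= 0.05
replicated <- sig & !is.na(volcano$p_repl) & volcano$p_repl <= 0.05 &
  sign(volcano$beta_disc) == sign(volcano$beta_repl)
cat(sprintf("discovery: %d/%d isomiRs at FDR <= 0.05; %d replicate at p <= 0.05\n",
            sum(sig), nrow(volcano), sum(replicated)))

top <- volcano$feature[order(volcano$q)][1]
rule <- disc$rules[[top]]
km <- lapply(list(discovery = list(disc_m, disc_cl),
                  replication = list(repl_m, repl_cl)), function(x) {
  grp <- dichotomize(x[[1]]$values[, top], rule)$high
  lr <- logrank_test(x[[2]]$time, x[[2]]$event, grp)
  list(chisq = lr$chisq, p = lr$p, medians = as.list(lr$medians),
       median_difference = lr$median_difference)
})
cat(sprintf("top marker %s: discovery log-rank chi2 = %.2f (p = %.2g), replication chi2 = %.2f (p = %.2g)\n",
            top, km$discovery$chisq, km$discovery$p,
            km$replication$chisq, km$replication$p))
jsonlite::write_json(list(top_marker = top, threshold = rule$threshold,
                          km = km),
                     "results/top_marker_km.json", auto_unbox = TRUE,
                     null = "null")
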