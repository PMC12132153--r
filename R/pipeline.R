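#' Analysis configuration
#'
#' Master configuration for the discovery -> replication analysis: the
#' abundance threshold, imputation parameters, selection-ensemble
#' parameters, learner set, evaluation settings, and the master seed. The
#' reference-scale selection parameters (subsets of 20, coverage 50,
#' 10-fold CV, 90% selection rate) are the defaults of
#' [selection_params()]; desk-scale analyses pass smaller values. Every
#' report produced under a configuration carries [config_hash()] of it.
#'
#' @param min_mean Abundance-filter threshold (UMIs).
#' @param impute [impute_params()].
#' @param selection [selection_params()].
#' @param learners Named list of `survival_learner`s.
#' @param screen_top Number of features kept by univariate screening where
#'   a multivariate model needs a small design (feature-view comparison).
#' @param fdr_alpha Discovery FDR level; `replication_alpha` the nominal
#'   replication level.
#' @param seed Master seed.
#' @export
analysis_config <- function(min_mean = 5, impute = impute_params(),
                            selection = selection_params(),
                            learners = list(cox = learner_cox()),
                            screen_top = 5L, fdr_alpha = 0.05,
                            replication_alpha = 0.05, seed = 1L) {
  list(min_mean = min_mean, impute = impute, selection = selection,
       learners = learners, screen_top = screen_top, fdr_alpha = fdr_alpha,
       replication_alpha = replication_alpha, seed = seed)
}

# Univariate dichotomized Cox per feature; rules optionally transferred.
univariate_cox_scan <- function(values, times, events, rules = NULL,
                                source = "discovery") {
  p <- ncol(values)
  y <- survival::Surv(times, events)
  out <- data.frame(feature = colnames(values), beta = NA_real_,
                    hr = NA_real_, p = NA_real_, threshold = NA_real_,
                    stringsAsFactors = FALSE)
  new_rules <- vector("list", p)
  names(new_rules) <- colnames(values)
  for (j in seq_len(p)) {
    d <- tryCatch({
      if (is.null(rules)) dichotomize(values[, j], "median", source = source)
      else dichotomize(values[, j], rules[[j]])
    }, error = function(e) NULL)
    if (is.null(d) || length(unique(d$high)) < 2L) next
    new_rules[[j]] <- d$rule
    out$threshold[j] <- d$rule$threshold
    fit <- tryCatch(
      survival::coxph.fit(matrix(as.numeric(d$high), ncol = 1), y,
                          strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(eps = 1e-9),
                          weights = NULL, method = "breslow",
                          rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients)) next
    b <- fit$coefficients
    se <- sqrt(fit$var[1, 1])
    out$beta[j] <- b
    out$hr[j] <- exp(b)
    out$p[j] <- 2 * stats::pnorm(-abs(b / se))
  }
  list(table = out, rules = new_rules)
}

#' Discovery -> replication prognostication analysis
#'
#' Runs the full analysis on a simulated (or loaded) pair of cohorts:
#' preprocessing of each cohort, feature intersection and standardization;
#' univariate dichotomized Cox with BH-FDR on the discovery cohort;
#' transfer of the discovery dichotomization thresholds to the replication
#' cohort (thresholds are applied, never recomputed) and identification of
#' replicated markers; Kaplan-Meier / log-rank curves for the top marker in
#' both cohorts; the selection ensemble and a Cox panel model fitted on
#' discovery, evaluated frozen on replication (C-index, mean AUC(t));
#' Shapley attributions and attribution-derived hazard ratios in both
#' cohorts; and the marker/NfL ratio biomarker with a discovery-optimized
#' cutpoint transferred to replication.
#'
#' @param sim Output of [simulate_cohorts()] (or a list with `discovery` /
#'   `replication`, each holding `counts` and `clinical`).
#' @param config [analysis_config()].
#' @return Object of class `analysis_report`.
#' @export
run_discovery_replication <- function(sim, config = analysis_config()) {
  disc <- sim$discovery; repl <- sim$replication
  prep_d <- preprocess_cohort(disc$counts, disc$clinical, config$min_mean,
                              config$impute)
  prep_r <- preprocess_cohort(repl$counts, repl$clinical, config$min_mean,
                              config$impute)
  shared <- intersect(colnames(prep_d$values), colnames(prep_r$values))
  if (!length(shared)) stop_invalid("no shared features after preprocessing")
  std <- intersect_and_standardize(prep_d, prep_r)
  Xd <- std[[1]]$values; Xr <- std[[2]]$values
  vd <- prep_d$values[, shared, drop = FALSE]  # pre-standardization scale
  vr <- prep_r$values[, shared, drop = FALSE]
  td <- disc$clinical$time; ed <- disc$clinical$event
  tr <- repl$clinical$time; er <- repl$clinical$event

  uni_d <- univariate_cox_scan(vd, td, ed, source = "discovery")
  uni_d$table$q <- bh_fdr(uni_d$table$p)
  uni_r <- univariate_cox_scan(vr, tr, er, rules = uni_d$rules)
  replicated <- uni_d$table$feature[
    !is.na(uni_d$table$q) & uni_d$table$q <= config$fdr_alpha &
      !is.na(uni_r$table$p) & uni_r$table$p <= config$replication_alpha &
      sign(uni_d$table$beta) == sign(uni_r$table$beta)]

  cand <- if (length(replicated)) {
    replicated[order(uni_d$table$q[match(replicated, uni_d$table$feature)])]
  } else uni_d$table$feature[order(uni_d$table$q)]
  top_marker <- cand[1]
  km <- lapply(list(discovery = list(vd, td, ed), replication = list(vr, tr, er)),
               function(co) {
    rule <- uni_d$rules[[top_marker]]
    if (is.null(rule)) return(NULL)
    grp <- dichotomize(co[[1]][, top_marker], rule)$high
    if (length(unique(grp)) < 2L) return(NULL)
    list(logrank = logrank_test(co[[2]], co[[3]], grp),
         km_high = km_estimate(co[[2]][grp == 1], co[[3]][grp == 1]),
         km_low = km_estimate(co[[2]][grp == 0], co[[3]][grp == 0]))
  })

  sel <- run_selection(Xd, td, ed, learners = config$learners,
                       params = config$selection)
  panel <- sel$feature_names[sel$final_panel]
  model <- NULL; evaluation <- NULL; shap <- NULL
  if (length(panel)) {
    model <- cox_fit(Xd[, panel, drop = FALSE], td, ed)
    risk_r <- as.vector(as.matrix(Xr[, panel, drop = FALSE]) %*%
                          model$table$beta)
    auc <- cumulative_dynamic_auc(risk_r, tr, er)
    evaluation <- list(cindex = cindex(risk_r, tr, er),
                       auc_times = auc$times, auc = auc$auc,
                       mean_auc = auc$mean_auc)
    shap <- lapply(list(discovery = Xd, replication = Xr), function(X) {
      at <- shapley_attributions(model, X[, panel, drop = FALSE], "exact")
      list(attributions = at,
           hr = shap_to_hr(at, X[, panel, drop = FALSE]),
           importance = importance_rank(at))
    })
  }

  ratio <- NULL
  if (!is.null(disc$clinical$nfl)) {
    raw_d <- disc$counts$values[, top_marker]
    raw_r <- repl$counts$values[, top_marker]
    raw_d[is.na(raw_d)] <- 0; raw_r[is.na(raw_r)] <- 0
    ratio_d <- ratio_biomarker(raw_d, disc$clinical$nfl)
    ratio_r <- ratio_biomarker(raw_r, repl$clinical$nfl)
    rule <- tryCatch(optimize_cutpoint(ratio_d, td, ed),
                     error = function(e) NULL)
    if (!is.null(rule)) {
      grp_r <- dichotomize(ratio_r, rule)$high
      ratio <- list(rule = rule,
                    discovery_logrank = logrank_test(td, ed,
                      dichotomize(ratio_d, rule)$high),
                    replication_logrank = if (length(unique(grp_r)) == 2L)
                      logrank_test(tr, er, grp_r) else NULL)
    }
  }

  cfg_echo <- config[setdiff(names(config), "learners")]
  structure(list(
    univariate = uni_d$table, replication = uni_r$table,
    replicated_features = replicated, top_marker = top_marker, km = km,
    selection = sel, panel = panel, model = model, evaluation = evaluation,
    shap = shap, ratio = ratio, shared_features = shared,
    config = cfg_echo, config_hash = config_hash(cfg_echo),
    seed = config$seed),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", length(x$shared_features), "shared features;",
      length(x$replicated_features), "replicated marker(s); panel of",
      length(x$panel), "\n")
  cat("  top marker:", x$top_marker, "| config", x$config_hash, "\n")
  if (!is.null(x$evaluation))
    cat(sprintf("  replication C-index %.3f, mean AUC(t) %.3f\n",
                x$evaluation$cindex, x$evaluation$mean_auc))
  invisible(x)
}

# Gene label of a canonical isomiR name (the part before the first token).
feature_gene <- function(names) sub("\\..*$", "", names)

#' Build the three feature views of a count matrix
#'
#' From isomiR-level counts (missing as zero): the isomiR-level view
#' itself; the gene-aggregate view ("miRNA", the sum of all isomiRs per
#' gene annotation); and the reference-only view (per gene, the single
#' most abundant isomiR by mean across the reference cohort's samples,
#' ties broken by name).
#'
#' @param values Samples x features count matrix (canonical isomiR names).
#' @param ref_means Per-feature means used to pick the reference isomiR
#'   (typically discovery-cohort means).
#' @return List of three matrices: `isomir`, `mirna`, `reference`.
#' @export
feature_views <- function(values, ref_means = colMeans(values)) {
  genes <- feature_gene(colnames(values))
  mirna <- t(rowsum(t(values), genes))
  ord <- order(-ref_means, colnames(values))
  pick <- !duplicated(genes[ord])
  ref_cols <- sort(colnames(values)[ord][pick])
  list(isomir = values, mirna = mirna,
       reference = values[, ref_cols, drop = FALSE])
}

# Screen + fit + evaluate one view: univariate Cox screening on discovery,
# multivariate Cox on the top features, frozen evaluation on replication.
evaluate_view <- function(Xd, Xr, td, ed, tr, er, screen_top) {
  zd <- scale(log1p(Xd)); zr <- scale(log1p(Xr))
  keep <- apply(zd, 2, function(c) all(is.finite(c)) && stats::sd(c) > 0) &
    apply(zr, 2, function(c) all(is.finite(c)) && stats::sd(c) > 0)
  zd <- zd[, keep, drop = FALSE]; zr <- zr[, keep, drop = FALSE]
  y <- survival::Surv(td, ed)
  zstat <- vapply(seq_len(ncol(zd)), function(j) {
    f <- tryCatch(survival::coxph.fit(zd[, j, drop = FALSE], y,
                                      strata = NULL, offset = NULL,
                                      init = NULL,
                                      control = survival::coxph.control(eps = 1e-9),
                                      weights = NULL, method = "breslow",
                                      rownames = NULL),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$coefficients)) return(0)
    abs(f$coefficients / sqrt(f$var[1, 1]))
  }, 0)
  top <- order(-zstat)[seq_len(min(screen_top, ncol(zd)))]
  fit <- cox_fit(zd[, top, drop = FALSE], td, ed)
  risk <- as.vector(zr[, top, drop = FALSE] %*% fit$table$beta)
  auc <- suppressWarnings(cumulative_dynamic_auc(risk, tr, er))
  list(mean_auc = auc$mean_auc, cindex = cindex(risk, tr, er),
       n_features = ncol(zd), top = colnames(zd)[top])
}

#' Compare isomiR-level, gene-aggregate, and reference-only feature views
#'
#' Builds the three views of both cohorts' counts and evaluates each
#' identically: univariate screening and a Cox model on the discovery
#' cohort, frozen risk evaluation (mean AUC(t), C-index) on the
#' replication cohort.
#'
#' @param sim Output of [simulate_cohorts()].
#' @param config [analysis_config()] (`screen_top` controls the screened
#'   model size).
#' @return Data frame with one row per view: `view`, `n_features`,
#'   `mean_auc`, `cindex`.
#' @export
compare_feature_views <- function(sim, config = analysis_config()) {
  vd <- sim$discovery$counts$values; vd[is.na(vd)] <- 0
  vr <- sim$replication$counts$values; vr[is.na(vr)] <- 0
  views_d <- feature_views(vd)
  views_r <- feature_views(vr, ref_means = colMeans(vd))
  res <- lapply(names(views_d), function(nm) {
    ev <- evaluate_view(views_d[[nm]], views_r[[nm]],
                        sim$discovery$clinical$time,
                        sim$discovery$clinical$event,
                        sim$replication$clinical$time,
                        sim$replication$clinical$event,
                        config$screen_top)
    data.frame(view = nm, n_features = ev$n_features,
               mean_auc = ev$mean_auc, cindex = ev$cindex,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "config_hash") <- config_hash(config[setdiff(names(config),
                                                         "learners")])
  out
}
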