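#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator; the median is the first time at which the
#' survival curve drops to 0.5 or below, and is `NA` when the curve never
#' reaches 0.5.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List `time`, `surv`, `n_risk`, `n_event`, `median`, and `fun`
#'   (a right-continuous step function S(t)).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_invalid("empty survival input")
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(sf$surv <= 0.5)) sf$time[which(sf$surv <= 0.5)[1]] else NA_real_
  list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
       n_event = sf$n.event, median = med,
       fun = stats::stepfun(sf$time, c(1, sf$surv)))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param times,events Survival outcome.
#' @param group Two-level grouping vector.
#' @return List `chisq`, `p` (1 df), `medians` (per group), and
#'   `median_difference` (absolute; `NA` if either median is undefined).
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop_invalid("log-rank test needs exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  meds <- vapply(levels(group), function(g) {
    km_estimate(times[group == g], events[group == g])$median
  }, 0)
  list(chisq = chisq, p = p, medians = meds,
       median_difference = abs(meds[1] - meds[2])[[1]])
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Fits a Cox model by Newton-Raphson maximization of the Breslow partial
#' likelihood (via `survival::coxph`), with Wald confidence intervals and
#' p-values and Harrell's C-index from the linear predictor.
#'
#' @param X Covariate matrix or data frame (no constant columns).
#' @param times,events Survival outcome.
#' @param ties Tie handling; only `"breslow"` is supported.
#' @param tol Convergence tolerance (default 1e-9).
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return An object of class `cox_fit`: `table` (per-covariate `beta`,
#'   `hr`, `ci_lower`, `ci_upper`, `se`, `p`), `loglik`, `cindex`,
#'   `converged`, `separation`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(X, times, events, ties = "breslow", tol = 1e-9,
                    max_iter = 50L) {
  ties <- match.arg(ties, "breslow")
  X <- as.data.frame(X)
  if (!sum(events) >= 1) stop_invalid("at least one event is required")
  num_const <- vapply(X, function(c) length(unique(c)) <= 1L, TRUE)
  if (any(num_const))
    stop_invalid("constant covariate(s): %s",
                 paste(names(X)[num_const], collapse = ", "))
  df <- data.frame(X, check.names = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ ., data = df,
                    ties = "breslow",
                    control = survival::coxph.control(eps = tol,
                                                      iter.max = max_iter)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- fit$iter < max_iter && all(is.finite(beta))
  if (!converged)
    stop_invalid("Cox fit did not converge in %d iterations (|beta| max %.2f)",
                 fit$iter, max(abs(beta)))
  z <- beta / se
  tab <- data.frame(
    beta = beta, hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    se = se, p = 2 * stats::pnorm(-abs(z)), row.names = names(beta))
  structure(list(table = tab, loglik = fit$loglik[2],
                 cindex = as.numeric(fit$concordance["concordance"]),
                 converged = converged,
                 separation = any(abs(beta) > 10),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> C-index", round(x$cindex, 3), "\n")
  print(round(x$table, 4))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues P-values in [0, 1].
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Harrell's C-index of a risk score
#'
#' Probability that, of a comparable patient pair, the one with the higher
#' risk score has the shorter survival; risk ties count 1/2.
#'
#' @param risk Per-sample risk scores (higher = earlier event).
#' @param times,events Survival outcome.
#' @return Concordance in [0, 1].
#' @export
cindex <- function(risk, times, events) {
  cf <- survival::concordancefit(survival::Surv(times, events), x = risk,
                                 reverse = TRUE)
  as.numeric(cf$concordance)
}

# Left-limit of the censoring-distribution Kaplan-Meier at each time point.
censoring_km_left <- function(times, events) {
  sf <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  function(t) {
    vapply(t, function(u) {
      i <- which(sf$time < u)
      if (length(i)) sf$surv[max(i)] else 1
    }, 0)
  }
}

#' IPCW cumulative/dynamic time-dependent AUC
#'
#' At each evaluation time t, cases are subjects with an observed event at
#' or before t (weighted by the inverse of the censoring-survival left
#' limit at their event time) and controls are subjects still at risk after
#' t. Risk ties count 1/2. Evaluation times at or beyond the last observed
#' time, or without cases or controls, are excluded with a warning. The
#' summary AUC is the unweighted mean over the retained grid.
#'
#' @param risk Risk scores (higher = earlier event).
#' @param times,events Survival outcome.
#' @param eval_times Evaluation grid; defaults to the unique event times
#'   strictly inside the follow-up range.
#' @return List `times`, `auc`, `mean_auc`.
#' @export
cumulative_dynamic_auc <- function(risk, times, events, eval_times = NULL) {
  stopifnot(length(risk) == length(times))
  if (is.null(eval_times)) {
    et <- sort(unique(times[events == 1]))
    eval_times <- et[et < max(times)]
  }
  drop <- eval_times >= max(times)
  if (any(drop)) {
    warning(sprintf("%d evaluation time(s) beyond last observed time excluded",
                    sum(drop)))
    eval_times <- eval_times[!drop]
  }
  G <- censoring_km_left(times, events)
  w_all <- 1 / G(times)
  auc <- rep(NA_real_, length(eval_times))
  ok <- rep(TRUE, length(eval_times))
  for (k in seq_along(eval_times)) {
    t <- eval_times[k]
    is_case <- times <= t & events == 1
    is_ctrl <- times > t
    if (!any(is_case) || !any(is_ctrl)) { ok[k] <- FALSE; next }
    w <- w_all[is_case]
    rc <- risk[is_case]; rs <- risk[is_ctrl]
    conc <- outer(rc, rs, ">") + 0.5 * outer(rc, rs, "==")
    auc[k] <- sum(w * rowSums(conc)) / (sum(w) * length(rs))
  }
  if (any(!ok)) warning(sprintf("%d evaluation time(s) without both cases and controls excluded",
                                sum(!ok)))
  list(times = eval_times[ok], auc = auc[ok], mean_auc = mean(auc[ok]))
}

#' Dichotomize a marker by median or by a transferred rule
#'
#' With `rule = "median"` the threshold is the sample median (even n: mean
#' of the two central order statistics) and the high group is `value >=
#' threshold`; an explicit rule (e.g. obtained on a discovery cohort) is
#' applied unchanged, implementing threshold transfer to a replication
#' cohort.
#'
#' @param values Finite marker values.
#' @param rule `"median"` or a `dichotomization_rule`.
#' @param source Label recorded as the rule's source cohort.
#' @return List `high` (0/1 vector) and `rule`
#'   (`list(threshold, orientation = ">=", source)`).
#' @export
dichotomize <- function(values, rule = "median", source = "discovery") {
  stopifnot(all(is.finite(values)))
  if (identical(rule, "median")) {
    if (length(unique(values)) == 1L)
      stop_invalid("all values identical: degenerate split")
    thr <- stats::median(values)
    rule <- structure(list(threshold = thr, orientation = ">=",
                           source = source),
                      class = "dichotomization_rule")
  }
  stopifnot(inherits(rule, "dichotomization_rule"))
  list(high = as.integer(values >= rule$threshold), rule = rule)
}

#' Optimize a dichotomization cutpoint by univariate Cox hazard ratio
#'
#' Scans every observed unique value as a candidate threshold, fits a
#' univariate Cox model on each dichotomization, and returns the admissible
#' threshold maximizing |log HR|. Candidates leaving either arm below
#' `min_frac` of the cohort are inadmissible (guards against degenerate
#' near-infinite-HR splits); ties break to the smaller threshold.
#'
#' @param values Marker values.
#' @param times,events Survival outcome.
#' @param min_frac Minimum fraction of patients per arm (default 0.1).
#' @param source Label for the resulting rule.
#' @return A `dichotomization_rule` with attributes `log_hr` and
#'   `threshold_table`.
#' @export
optimize_cutpoint <- function(values, times, events, min_frac = 0.1,
                              source = "discovery") {
  n <- length(values)
  cand <- sort(unique(values))
  y <- survival::Surv(times, events)
  min_arm <- ceiling(min_frac * n)
  best <- NULL
  rows <- list()
  for (thr in cand) {
    high <- as.numeric(values >= thr)
    if (sum(high) < min_arm || sum(1 - high) < min_arm) next
    fit <- tryCatch(
      survival::coxph.fit(matrix(high, ncol = 1), y, strata = NULL,
                          offset = NULL, init = NULL,
                          control = survival::coxph.control(eps = 1e-9),
                          weights = NULL, method = "breslow",
                          rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients)) next
    b <- fit$coefficients
    rows[[length(rows) + 1L]] <- data.frame(threshold = thr, log_hr = b)
    if (is.null(best) || abs(b) > abs(best$log_hr) + 1e-12) {
      best <- list(threshold = thr, log_hr = b)
    }
  }
  if (is.null(best))
    stop_invalid("no admissible threshold (arm-size guard: >= %d per arm)",
                 min_arm)
  rule <- structure(list(threshold = best$threshold, orientation = ">=",
                         source = source),
                    class = "dichotomization_rule")
  attr(rule, "log_hr") <- best$log_hr
  attr(rule, "threshold_table") <- do.call(rbind, rows)
  rule
}

#' Ratio biomarker
#'
#' Elementwise ratio of two raw-scale markers (e.g. an isomiR count divided
#' by NfL concentration).
#'
#' @param numerator,denominator Equal-length numeric vectors; the
#'   denominator must be strictly positive.
#' @return Numeric ratio vector.
#' @export
ratio_biomarker <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  bad <- which(!(denominator > 0))
  if (length(bad))
    stop_invalid("zero/negative denominator for sample(s): %s",
                 paste(utils::head(bad, 10), collapse = ", "))
  numerator / denominator
}

#' Proportional-hazards assumption check
#'
#' Scaled Schoenfeld-residual test of each covariate's effect against time
#' (`survival::cox.zph`).
#'
#' @param fit A [cox_fit()].
#' @return Named per-covariate p-values (plus `GLOBAL`).
#' @export
ph_check <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  zp <- survival::cox.zph(fit$fit)
  stats::setNames(zp$table[, "p"], rownames(zp$table))
}
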