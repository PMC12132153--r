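#' Bootstrap subset design with per-feature coverage guarantee
#'
#' Samples feature subsets with repetition until every feature appears in
#' at least `min_coverage` subsets. Each subset contains one focal feature
#' (drawn among the currently least-covered) plus `subset_size - 1` distinct
#' companions sampled at random, preferring features still short of
#' coverage so the design stays economical: for n features at least
#' `n * min_coverage / subset_size` subsets are needed (at the reference
#' scale of 1,480 features, subsets of 20, and coverage 50, that bound is
#' 3,700) and the sampler realizes close to it.
#'
#' @param n_features Number of features.
#' @param subset_size Features per subset (default 20; must be
#'   <= `n_features`).
#' @param min_coverage Minimum number of subsets containing each feature
#'   (default 50).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return Object of class `subset_design`: `subsets` (list of integer
#'   vectors), `coverage` (per-feature counts), and the parameters.
#' @export
make_subsets <- function(n_features, subset_size = 20L, min_coverage = 50L,
                         seed = 1L) {
  if (!is_count_scalar(min_coverage) || min_coverage < 1)
    stop_invalid("min_coverage must be a positive integer")
  if (subset_size > n_features)
    stop_invalid("subset_size (%d) cannot exceed n_features (%d)",
                 subset_size, n_features)
  n_features <- as.integer(n_features)
  subset_size <- as.integer(subset_size)
  with_seed(seed, {
    if (subset_size == n_features) {
      subsets <- replicate(min_coverage, seq_len(n_features),
                           simplify = FALSE)
      coverage <- rep(as.integer(min_coverage), n_features)
    } else {
      resample <- function(x, k) x[sample.int(length(x), k)]
      coverage <- integer(n_features)
      subsets <- vector("list", ceiling(n_features * min_coverage /
                                          subset_size) + 64L)
      ns <- 0L
      k <- subset_size - 1L
      while (min(coverage) < min_coverage) {
        minima <- which(coverage == min(coverage))
        focal <- if (length(minima) == 1L) minima else resample(minima, 1L)
        under <- setdiff(which(coverage < min_coverage), focal)
        pick <- if (length(under) >= k) {
          resample(under, k)
        } else {
          c(under, resample(setdiff(seq_len(n_features), c(focal, under)),
                            k - length(under)))
        }
        s <- c(focal, pick)
        ns <- ns + 1L
        if (ns > length(subsets)) subsets <- c(subsets, vector("list", 256L))
        subsets[[ns]] <- s
        coverage[s] <- coverage[s] + 1L
      }
      subsets <- subsets[seq_len(ns)]
    }
    structure(list(subsets = subsets, coverage = coverage,
                   subset_size = subset_size, min_coverage = min_coverage,
                   seed = seed),
              class = "subset_design")
  })
}

#' @export
print.subset_design <- function(x, ...) {
  cat(sprintf("<subset_design> %d subsets of %d features; min coverage %d\n",
              length(x$subsets), x$subset_size, min(x$coverage)))
  invisible(x)
}

#' Survival learner contract and built-in learners
#'
#' A survival learner is a list with `fit(X, times, events)` returning a
#' model object and `risk(model, X)` returning per-sample risk scores
#' (higher risk = predicted earlier event), deterministic under a fixed
#' seed. `learner_cox()` is an unregularized Breslow-ties Cox learner (the
#' native learner of the selection ensemble); `learner_rsf()` wraps a
#' random survival forest (risk = summed cumulative hazard);
#' `learner_xgb()` wraps gradient-boosted Cox regression.
#'
#' @param params Named hyperparameter list; defaults are the ensemble
#'   presets ([preset_rsf()], [preset_xgb_selection()]).
#' @return Object of class `survival_learner`.
#' @export
learner_cox <- function(params = preset_cox()) {
  control <- survival::coxph.control(eps = params$tol %||% 1e-9,
                                     iter.max = params$max_iter %||% 25L)
  method <- params$ties %||% "breslow"
  fit_fun <- function(X, times, events) {
    X <- as.matrix(X)
    keep <- .colVars(X) > 0
    if (!any(keep) || sum(events) == 0)
      stop("degenerate training data for Cox learner")
    Xk <- X[, keep, drop = FALSE]
    f <- survival::coxph.fit(
      Xk, survival::Surv(times, events), strata = NULL, offset = NULL,
      init = NULL, control = control,
      weights = NULL, method = method, rownames = NULL)
    if (any(!is.finite(f$coefficients)))
      stop("Cox learner produced non-finite coefficients")
    list(beta = f$coefficients, keep = keep, means = colMeans(Xk))
  }
  risk_fun <- function(model, X) {
    X <- as.matrix(X)[, model$keep, drop = FALSE]
    as.vector(X %*% model$beta)
  }
  structure(list(name = "cox", fit = fit_fun, risk = risk_fun,
                 params = params),
            class = "survival_learner")
}

#' @rdname learner_cox
#' @export
learner_rsf <- function(params = preset_rsf()) {
  fit_fun <- function(X, times, events) {
    df <- data.frame(time = times, event = events, as.data.frame(X))
    ranger::ranger(survival::Surv(time, event) ~ ., data = df,
                   num.trees = params$n_estimators %||% 20L,
                   max.depth = params$max_depth %||% 4L,
                   min.node.size = params$min_samples_leaf %||% 2L,
                   mtry = max(1L, floor((params$max_features %||% 0.5) *
                                          ncol(as.matrix(X)))),
                   sample.fraction = params$max_samples %||% 0.5,
                   seed = params$random_state %||% 42L,
                   num.threads = 1L)
  }
  risk_fun <- function(model, X) {
    pr <- stats::predict(model, data = as.data.frame(X), num.threads = 1L)
    rowSums(pr$chf)
  }
  structure(list(name = "rsf", fit = fit_fun, risk = risk_fun,
                 params = params),
            class = "survival_learner")
}

#' @rdname learner_cox
#' @export
learner_xgb <- function(params = preset_xgb_selection()) {
  fit_fun <- function(X, times, events) {
    label <- ifelse(events == 1, times, -times)
    dm <- xgboost::xgb.DMatrix(as.matrix(X), label = label)
    xgboost::xgb.train(
      params = list(objective = "survival:cox",
                    eta = params$learning_rate %||% 0.5,
                    max_depth = params$max_depth %||% 2L,
                    subsample = params$subsample %||% 0.3,
                    seed = params$random_state %||% 0L,
                    nthread = 1L),
      data = dm, nrounds = params$n_estimators %||% 20L, verbose = 0)
  }
  risk_fun <- function(model, X) {
    log(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X))))
  }
  structure(list(name = "xgb", fit = fit_fun, risk = risk_fun,
                 params = params),
            class = "survival_learner")
}

#' Learner hyperparameter presets
#'
#' Named parameter blocks for the three selection-ensemble learners and the
#' tuned gradient-boosting configuration used for the final panel model.
#'
#' @return Named list of hyperparameters.
#' @export
preset_cox <- function() {
  list(regularization = "none", ties = "breslow", tol = 1e-9)
}

#' @rdname preset_cox
#' @export
preset_rsf <- function() {
  list(n_estimators = 20L, max_depth = 4L, min_samples_split = 2L,
       min_samples_leaf = 2L, max_features = 0.5, max_samples = 0.5,
       min_weight_fraction_leaf = 0, max_leaf_nodes = NULL,
       bootstrap = TRUE, random_state = 42L)
}

#' @rdname preset_cox
#' @export
preset_xgb_selection <- function() {
  list(n_estimators = 20L, learning_rate = 0.5, max_depth = 2L,
       subsample = 0.3, loss = "coxph", criterion = "friedman_mse",
       min_samples_split = 2L, min_samples_leaf = 1L,
       min_weight_fraction_leaf = 0, min_impurity_decrease = 0,
       max_features = NULL, max_leaf_nodes = NULL,
       validation_fraction = 0.1, n_iter_no_change = NULL, tol = 1e-4,
       dropout_rate = 0.3, ccp_alpha = 0, random_state = 0L)
}

#' @rdname preset_cox
#' @export
preset_xgb_tuned <- function() {
  list(n_estimators = 95L, learning_rate = 0.1, max_depth = 35L,
       subsample = 0.4545454545454545, loss = "coxph",
       criterion = "friedman_mse", min_samples_split = 60L,
       min_samples_leaf = 20L,
       min_weight_fraction_leaf = 0.060461799614030046,
       min_impurity_decrease = 0.6, max_features = 0.1111111111111111,
       max_leaf_nodes = 100L, validation_fraction = 0.1,
       n_iter_no_change = NULL, tol = 1e-4, dropout_rate = 0.016,
       ccp_alpha = 0.1, random_state = 42L)
}

# Event-stratified fold assignment so every fold holds events.
make_folds <- function(events, k, seed) {
  with_seed(seed, {
    fold <- integer(length(events))
    for (g in c(1, 0)) {
      idx <- sample(which(events == g))
      if (length(idx)) fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Column variances without apply() overhead.
.colVars <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

# Vectorized Harrell concordance for the small test folds of the CV loop
# (comparable pairs: shorter time has an event, or tied times with exactly
# one event; risk ties count 1/2). The exported cindex() is the
# independent reference route.
harrell_cindex_fast <- function(risk, times, events) {
  lt <- outer(times, times, "<")
  comp <- (lt & events == 1) |
    (outer(times, times, "==") & outer(events == 1, events == 0, "&"))
  den <- sum(comp)
  if (den == 0) return(NA_real_)
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  (sum(gt & comp) + 0.5 * sum(eq & comp)) / den
}

# Mean cross-validated C-index of a feature set; NA if every fold fails.
cv_cindex <- function(cols, X, times, events, learner, fold, k) {
  scores <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test) || sum(events[!test]) == 0 || sum(events[test]) == 0) next
    m <- tryCatch(learner$fit(X[!test, cols, drop = FALSE],
                              times[!test], events[!test]),
                  error = function(e) NULL)
    if (is.null(m)) { warning("learner failed in a CV fold; fold skipped"); next }
    r <- learner$risk(m, X[test, cols, drop = FALSE])
    scores[f] <- harrell_cindex_fast(r, times[test], events[test])
  }
  if (all(is.na(scores))) NA_real_ else mean(scores, na.rm = TRUE)
}

#' Sequential forward selection with cross-validation on one subset
#'
#' Starting from the empty set (baseline concordance 0.5), greedily adds
#' the feature whose inclusion maximizes the mean k-fold cross-validated
#' C-index (folds event-stratified, seeded once, and shared across all
#' candidate evaluations); stops at the first non-improving addition and
#' returns the feature set at the maximum of the greedy path together with
#' that C-index. Greedy ties break to the lowest feature index.
#'
#' @param subset Integer vector of candidate feature columns.
#' @param X Feature matrix (samples x features).
#' @param times,events Survival outcome.
#' @param learner A `survival_learner` (default [learner_cox()]).
#' @param k Number of CV folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List `selected` (feature columns), `cindex` (best CV C-index),
#'   and `path` (per-step scores).
#' @export
sfs_cv <- function(subset, X, times, events, learner = learner_cox(),
                   k = 10L, seed = 1L) {
  stopifnot(all(subset >= 1 & subset <= ncol(X)), k <= length(times))
  fold <- make_folds(events, k, seed)
  selected <- integer(0)
  best <- 0.5
  path <- numeric(0)
  remaining <- sort(unique(subset))  # ascending: greedy ties break low
  repeat {
    if (!length(remaining)) break
    scores <- vapply(remaining, function(f)
      cv_cindex(c(selected, f), X, times, events, learner, fold, k),
      0)
    if (all(is.na(scores))) {
      if (!length(selected)) {
        warning("all folds failed for every candidate; subset skipped")
        return(list(selected = integer(0), cindex = NA_real_, path = path))
      }
      break
    }
    j <- which.max(replace(scores, is.na(scores), -Inf))  # lowest index wins ties
    if (scores[j] <= best) break
    best <- scores[j]
    selected <- c(selected, remaining[j])
    path <- c(path, best)
    remaining <- remaining[-j]
  }
  list(selected = selected, cindex = best, path = path)
}

#' Frequency-based feature selection
#'
#' Keeps features whose selection rate (times selected / times included
#' across all subsets containing them) is at least `threshold`.
#'
#' @param tallies Data frame with columns `feature`, `included`,
#'   `selected`.
#' @param threshold Selection-rate threshold (default 0.90).
#' @param min_coverage Required minimum `included` per feature.
#' @return Features (values of `tallies$feature`) passing the threshold.
#' @export
frequency_select <- function(tallies, threshold = 0.90, min_coverage = 1L) {
  if (any(tallies$included < min_coverage))
    stop_invalid("every feature must be included in >= %d subsets before frequency selection",
                 min_coverage)
  rate <- tallies$selected / tallies$included
  tallies$feature[rate >= threshold]
}

#' Elbow threshold of a score curve
#'
#' Sorts the values in descending order, normalizes both axes to [0, 1],
#' and returns the value at the point of maximum perpendicular distance
#' from the chord joining the first and last points (kneedle-style). The
#' result is invariant to affine rescaling of the values. A linear ramp has
#' no interior elbow and resolves near an endpoint.
#'
#' @param values At least three score values (e.g. subset C-indexes).
#' @return The threshold value (an element of `values`).
#' @export
elbow_threshold <- function(values) {
  if (length(values) < 3L) stop_invalid("elbow needs at least 3 values")
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  if (v[1] == v[n]) return(v[n])
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[n]) / (v[1] - v[n])
  # chord from (0, 1) to (1, 0): perpendicular distance ~ |1 - x - y|
  d <- abs(1 - x - y)
  if (max(d) < 1e-9) {
    warning("no distinct elbow (curve is a straight ramp); returning the smallest value")
    return(v[n])
  }
  v[which.max(d)]
}

#' Selection ensemble parameters
#'
#' @param subset_size Features per subset (reference scale: 20).
#' @param min_coverage Minimum subsets per feature (reference scale: 50).
#' @param cv_folds CV folds inside each subset's forward selection
#'   (reference scale: 10).
#' @param selection_threshold Frequency-selection rate (reference: 0.90).
#' @param round2_n_subsets Optional fixed subset count for the refinement
#'   round (otherwise the coverage rule is re-applied to the survivors).
#' @param seed Master seed.
#' @export
selection_params <- function(subset_size = 20L, min_coverage = 50L,
                             cv_folds = 10L, selection_threshold = 0.90,
                             round2_n_subsets = NULL, seed = 1L) {
  list(subset_size = subset_size, min_coverage = min_coverage,
       cv_folds = cv_folds, selection_threshold = selection_threshold,
       round2_n_subsets = round2_n_subsets, seed = seed)
}

run_round <- function(design, X, times, events, learners, k, seed) {
  lapply(learners, function(lrn) {
    res <- vector("list", length(design$subsets))
    for (i in seq_along(design$subsets)) {
      res[[i]] <- sfs_cv(design$subsets[[i]], X, times, events, lrn, k,
                         seed = derive_seed(seed, i))
    }
    res
  })
}

tally_round <- function(design, round_res, n_features) {
  lapply(round_res, function(res) {
    included <- integer(n_features)
    selected <- integer(n_features)
    for (i in seq_along(design$subsets)) {
      included[design$subsets[[i]]] <- included[design$subsets[[i]]] + 1L
      sel <- res[[i]]$selected
      if (length(sel)) selected[sel] <- selected[sel] + 1L
    }
    data.frame(feature = seq_len(n_features), included = included,
               selected = selected)
  })
}

#' Run the full bootstrap-subset selection ensemble
#'
#' Round 1 samples covered subsets over all features and runs
#' cross-validated sequential forward selection per subset and learner;
#' frequency selection (rate >= `selection_threshold`) yields per-learner
#' survivor panels whose union enters round 2. Round 2 re-subsets the
#' survivors (coverage rule, or `round2_n_subsets` override), records each
#' subset's best C-index, applies the elbow threshold per learner (features
#' kept if the best C-index of a subset that selected them exceeds it), and
#' unions the per-learner panels into the final panel. With fewer than
#' three round-2 subsets the elbow is skipped and all survivors are kept.
#'
#' @param X Preprocessed (standardized) feature matrix.
#' @param times,events Survival outcome.
#' @param learners Named list of `survival_learner`s (default: Cox only).
#' @param params [selection_params()].
#' @return Object of class `selection_report`.
#' @export
run_selection <- function(X, times, events,
                          learners = list(cox = learner_cox()),
                          params = selection_params()) {
  X <- as.matrix(X)
  if (is.null(names(learners)))
    names(learners) <- vapply(learners, `[[`, "", "name")
  p <- ncol(X)
  design1 <- make_subsets(p, params$subset_size, params$min_coverage,
                          seed = derive_seed(params$seed, 1L))
  round1 <- run_round(design1, X, times, events, learners, params$cv_folds,
                      seed = derive_seed(params$seed, 2L))
  tallies <- tally_round(design1, round1, p)
  round1_panels <- lapply(tallies, frequency_select,
                          threshold = params$selection_threshold,
                          min_coverage = params$min_coverage)
  survivors <- sort(unique(unlist(round1_panels)))

  design2 <- NULL; round2_cindex <- NULL; elbow <- NULL
  round2_panels <- lapply(learners, function(l) survivors)
  if (length(survivors)) {
    size2 <- min(params$subset_size, length(survivors))
    design2 <- make_subsets(length(survivors), size2,
                            params$min_coverage,
                            seed = derive_seed(params$seed, 3L))
    if (!is.null(params$round2_n_subsets) &&
        params$round2_n_subsets < length(design2$subsets)) {
      design2$subsets <- design2$subsets[seq_len(params$round2_n_subsets)]
    }
    round2 <- run_round(design2, X[, survivors, drop = FALSE], times, events,
                        learners, params$cv_folds,
                        seed = derive_seed(params$seed, 4L))
    round2_cindex <- lapply(round2, function(res)
      vapply(res, `[[`, 0, "cindex"))
    if (length(design2$subsets) >= 3L) {
      elbow <- lapply(round2_cindex, elbow_threshold)
      round2_panels <- lapply(names(learners) %||% seq_along(learners),
                              function(nm) integer(0))
      names(round2_panels) <- names(round2_cindex)
      for (nm in names(round2_cindex)) {
        bestC <- rep(-Inf, length(survivors))
        res <- round2[[nm]]
        ci <- round2_cindex[[nm]]
        for (i in seq_along(res)) {
          sel <- res[[i]]$selected
          if (length(sel) && is.finite(ci[i]))
            bestC[sel] <- pmax(bestC[sel], ci[i])
        }
        round2_panels[[nm]] <- survivors[bestC > elbow[[nm]]]
      }
    }
  }
  final_panel <- sort(unique(unlist(round2_panels)))
  structure(list(
    tallies = tallies, round1_panels = round1_panels,
    survivors = survivors, design1 = design1, design2 = design2,
    round2_cindex = round2_cindex, elbow = elbow,
    round2_panels = round2_panels, final_panel = final_panel,
    feature_names = colnames(X), params = params,
    seeds = list(design1 = derive_seed(params$seed, 1L),
                 round1 = derive_seed(params$seed, 2L),
                 design2 = derive_seed(params$seed, 3L),
                 round2 = derive_seed(params$seed, 4L))),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d subsets -> %d survivors -> final panel of %d\n",
              length(x$design1$subsets), length(x$survivors),
              length(x$final_panel)))
  if (length(x$final_panel) && !is.null(x$feature_names))
    cat(" ", paste(x$feature_names[x$final_panel], collapse = ", "), "\n")
  invisible(x)
}

#' Export a selection report as JSON
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_selection_json <- function(report, path) {
  out <- list(
    n_subsets_round1 = length(report$design1$subsets),
    min_coverage = min(report$design1$coverage),
    survivors = report$feature_names[report$survivors] %||% report$survivors,
    elbow = report$elbow,
    final_panel = report$feature_names[report$final_panel] %||%
      report$final_panel,
    params = report$params, seeds = report$seeds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
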