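#' Shapley attributions of a survival risk function
#'
#' Attributes each sample's risk score (the model's linear predictor /
#' log-hazard scale) to its features. For linear risk models the exact
#' interventional Shapley value has the closed form
#' `phi_ij = beta_j * (x_ij - background_j)`; for arbitrary risk functions
#' a permutation-sampling estimator averages marginal contributions over
#' `n_mc` random feature orderings with absent features set to the
#' background (training means). Both methods satisfy the efficiency axiom
#' exactly per sample: `base_value + sum_j phi_ij = risk_i` (the
#' permutation estimator telescopes within every ordering).
#'
#' @param model Either a [cox_fit()], a fitted [learner_cox()] model, or a
#'   list `list(learner, model)` pairing any `survival_learner` with its
#'   fitted model (required for `method = "permutation"` on non-linear
#'   learners).
#' @param X Samples x features matrix to explain.
#' @param method `"exact"` (linear models only) or `"permutation"`.
#' @param n_mc Number of sampled permutations for the MC estimator.
#' @param seed Integer seed for the MC estimator.
#' @param background Background feature values (default `colMeans(X)`).
#' @return Object of class `attribution_matrix`: `values` (samples x
#'   features), `base_value`, `method`, `n_mc`, `seed`.
#' @export
shapley_attributions <- function(model, X, method = c("exact", "permutation"),
                                 n_mc = 200L, seed = 1L, background = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  bg <- background %||% colMeans(X)
  riskfun <- risk_function(model, ncol(X))
  if (method == "exact") {
    beta <- linear_coefficients(model, ncol(X))
    if (is.null(beta))
      stop_invalid("exact attributions require a linear (Cox) risk model; use method = 'permutation'")
    phi <- sweep(X, 2, bg) * matrix(beta, nrow(X), ncol(X), byrow = TRUE)
    base <- sum(beta * bg)
  } else {
    if (n_mc < 1) stop_invalid("n_mc must be >= 1")
    n <- nrow(X); p <- ncol(X)
    phi <- matrix(0, n, p)
    base <- riskfun(matrix(bg, 1, p,
                           dimnames = list(NULL, colnames(X))))[1]
    with_seed(seed, {
      bg_mat <- matrix(bg, n, p, byrow = TRUE, dimnames = dimnames(X))
      for (t in seq_len(n_mc)) {
        ord <- sample.int(p)
        cur <- bg_mat
        prev <- rep(base, n)
        for (j in ord) {
          cur[, j] <- X[, j]
          val <- riskfun(cur)
          phi[, j] <- phi[, j] + (val - prev)
          prev <- val
        }
      }
    })
    phi <- phi / n_mc
  }
  dimnames(phi) <- dimnames(X)
  structure(list(values = phi, base_value = base, method = method,
                 n_mc = if (method == "permutation") n_mc else NA_integer_,
                 seed = seed),
            class = "attribution_matrix")
}

# Resolve the per-sample risk function of a supported model object.
risk_function <- function(model, p) {
  if (inherits(model, "cox_fit")) {
    beta <- model$table$beta
    return(function(Xm) as.vector(as.matrix(Xm) %*% beta))
  }
  if (is.list(model) && !is.null(model$beta) && !is.null(model$keep)) {
    lrn <- learner_cox()
    return(function(Xm) lrn$risk(model, Xm))
  }
  if (is.list(model) && inherits(model$learner, "survival_learner")) {
    if (is.null(model$model)) stop_invalid("model must be fitted first")
    return(function(Xm) model$learner$risk(model$model, Xm))
  }
  stop_invalid("unsupported model object; fit it before explaining")
}

linear_coefficients <- function(model, p) {
  if (inherits(model, "cox_fit")) return(model$table$beta)
  if (is.list(model) && !is.null(model$beta) && !is.null(model$keep)) {
    beta <- numeric(p)
    beta[model$keep] <- model$beta
    return(beta)
  }
  if (is.list(model) && inherits(model$learner, "survival_learner") &&
      model$learner$name == "cox") {
    return(linear_coefficients(model$model, p))
  }
  NULL
}

#' Attribution-derived hazard ratios
#'
#' For each feature, exponentiates the per-sample attributions and divides
#' the mean over patients with feature values strictly above the feature
#' mean by the mean over patients at or below it. A feature whose
#' attributions are all zero yields a ratio of 1; a feature with an empty
#' group is reported as `NA`.
#'
#' @param attr An `attribution_matrix`.
#' @param feature_values Matrix of the feature values the attributions were
#'   computed on (same shape as `attr$values`).
#' @return Data frame `feature`, `hr_shap`, `n_above`, `n_below`.
#' @export
shap_to_hr <- function(attr, feature_values) {
  stopifnot(inherits(attr, "attribution_matrix"))
  fv <- as.matrix(feature_values)
  stopifnot(identical(dim(fv), dim(attr$values)))
  p <- ncol(fv)
  hr <- rep(NA_real_, p)
  n_above <- integer(p); n_below <- integer(p)
  for (j in seq_len(p)) {
    above <- fv[, j] > mean(fv[, j])
    n_above[j] <- sum(above); n_below[j] <- sum(!above)
    if (n_above[j] == 0L || n_below[j] == 0L) next
    hr[j] <- mean(exp(attr$values[above, j])) /
      mean(exp(attr$values[!above, j]))
  }
  data.frame(feature = colnames(fv) %||% paste0("f", seq_len(p)),
             hr_shap = hr, n_above = n_above, n_below = n_below,
             stringsAsFactors = FALSE)
}

#' Rank features by mean absolute attribution
#'
#' @param attr An `attribution_matrix`.
#' @return Data frame `feature`, `mean_abs_phi`, ordered descending (ties
#'   break by column index).
#' @export
importance_rank <- function(attr) {
  stopifnot(inherits(attr, "attribution_matrix"))
  imp <- colMeans(abs(attr$values))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = (colnames(attr$values) %||%
                          paste0("f", seq_along(imp)))[ord],
             mean_abs_phi = imp[ord], stringsAsFactors = FALSE)
}
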