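#' Abundance filter
#'
#' Keeps features whose mean UMI count across the cohort's samples (missing
#' cells counted as zero) is strictly above `min_mean`.
#'
#' @param m An [isomir_matrix()] in state `"raw"`.
#' @param min_mean Abundance threshold (default 5 UMIs; the boundary is
#'   exclusive: a feature with mean exactly `min_mean` is removed).
#' @return Filtered `isomir_matrix` (still `"raw"`).
#' @export
abundance_filter <- function(m, min_mean = 5) {
  require_state(m, "raw", "abundance_filter")
  v <- m$values
  v[m$missing] <- 0
  keep <- colMeans(v) > min_mean
  if (!any(keep)) warning("abundance filter removed every feature")
  isomir_matrix(m$values[, keep, drop = FALSE],
                missing = m$missing[, keep, drop = FALSE],
                batch = m$batch, cohort = m$cohort, state = "raw",
                medians = m$medians)
}

#' Imputation parameters
#'
#' Defaults follow the denoising-autoencoder configuration used for
#' missing-count imputation: three hidden layers of 512 nodes, corruption
#' probability 0.95, learning rate 1e-6, 40 training passes, and the mean
#' over 50 imputed datasets. Layer sizes, passes, and dataset count scale
#' down for tests. `method = "median"` selects the deterministic
#' feature-median fallback imputer, which satisfies the same contract.
#'
#' @param method `"dae"` or `"median"`.
#' @param layers Hidden layer sizes.
#' @param corruption Input corruption probability during training.
#' @param lr Learning rate.
#' @param passes Training passes (full-batch gradient steps).
#' @param n_datasets Number of imputed datasets averaged per missing cell.
#' @param seed Integer seed.
#' @export
impute_params <- function(method = c("median", "dae"),
                          layers = c(512L, 512L, 512L), corruption = 0.95,
                          lr = 1e-6, passes = 40L, n_datasets = 50L,
                          seed = 1L) {
  list(method = match.arg(method), layers = layers, corruption = corruption,
       lr = lr, passes = passes, n_datasets = n_datasets, seed = seed)
}

#' Impute missing UMI counts
#'
#' Replaces every originally missing cell with the mean of `n_datasets`
#' imputations from the configured imputer; observed cells are returned
#' unchanged. The default denoising autoencoder trains on the observed
#' cells (log1p scale, standardized, with clinical covariates age, sex,
#' site of onset, and riluzole one-hot encoded as auxiliary inputs) and
#' draws each imputed dataset from a forward pass with dropout active.
#' The `"median"` imputer replaces missing cells with the feature's
#' observed median; a feature with no observed value falls back to the
#' cohort-level prior (the overall observed median).
#'
#' @param m An [isomir_matrix()] in state `"raw"`.
#' @param clinical Optional clinical table (used by the DAE imputer).
#' @param params [impute_params()].
#' @return `isomir_matrix` in state `"imputed"` (no `NA` cells).
#' @export
impute_missing <- function(m, clinical = NULL, params = impute_params()) {
  require_state(m, "raw", "impute_missing")
  v <- m$values
  if (!any(m$missing)) {
    return(isomir_matrix(v, missing = m$missing, batch = m$batch,
                         cohort = m$cohort, state = "imputed",
                         medians = m$medians))
  }
  filled <- if (params$method == "median") {
    impute_median(v, m$missing)
  } else {
    impute_dae(v, m$missing, clinical, params)
  }
  isomir_matrix(filled, missing = m$missing, batch = m$batch,
                cohort = m$cohort, state = "imputed", medians = m$medians)
}

impute_median <- function(v, missing) {
  prior <- stats::median(v[!missing], na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    mj <- missing[, j]
    if (!any(mj)) next
    obs <- v[!mj, j]
    fill <- if (length(obs)) stats::median(obs) else prior
    v[mj, j] <- fill
  }
  v
}

# One-hot clinical covariates used as similarity inputs by the DAE imputer.
clinical_onehot <- function(clinical, n) {
  if (is.null(clinical)) return(matrix(0, n, 0))
  cols <- list()
  if (!is.null(clinical$age_enroll)) cols$age <- scale(clinical$age_enroll)
  if (!is.null(clinical$sex)) cols$sex_m <- as.numeric(clinical$sex == "M")
  if (!is.null(clinical$onset_site))
    cols$bulbar <- as.numeric(clinical$onset_site == "bulbar")
  if (!is.null(clinical$riluzole))
    cols$riluzole <- as.numeric(clinical$riluzole == "yes")
  if (!length(cols)) return(matrix(0, n, 0))
  do.call(cbind, lapply(cols, as.numeric))
}

# Minimal denoising autoencoder: tanh hidden layers, linear output,
# full-batch gradient descent on the observed-cell squared error, input
# corruption during training, and dropout-active forward passes to draw
# the imputed datasets.
impute_dae <- function(v, missing, clinical, params) {
  n <- nrow(v); p <- ncol(v)
  x <- log1p(v)
  col_med <- apply(x, 2, function(c) stats::median(c, na.rm = TRUE))
  col_med[!is.finite(col_med)] <- 0
  for (j in seq_len(p)) x[missing[, j], j] <- col_med[j]
  mu <- colMeans(x); sd <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  aux <- clinical_onehot(clinical, n)
  inp <- cbind(xs, aux)
  d <- ncol(inp)
  obs_w <- cbind(!missing, matrix(TRUE, n, ncol(aux)))  # loss on observed cells

  with_seed(params$seed, {
    sizes <- c(d, params$layers, d)
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(1 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    nl <- length(W)
    forward <- function(input, drop_mask = NULL) {
      a <- list(input)
      h <- input
      for (l in seq_len(nl)) {
        z <- sweep(h %*% W[[l]], 2, b[[l]], "+")
        h <- if (l < nl) tanh(z) else z
        if (!is.null(drop_mask) && l < nl) h <- h * drop_mask[[l]]
        a[[l + 1L]] <- h
      }
      a
    }
    for (step in seq_len(params$passes)) {
      corrupt <- matrix(stats::runif(n * d) >= params$corruption, n, d)
      act <- forward(inp * corrupt)
      out <- act[[nl + 1L]]
      delta <- (out - inp) * obs_w / sum(obs_w)
      for (l in seq.int(nl, 1L)) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * (1 - act[[l]]^2)
        W[[l]] <- W[[l]] - params$lr * gW
        b[[l]] <- b[[l]] - params$lr * gb
      }
    }
    # multiple imputation: dropout-active forward passes, mean over datasets
    acc <- matrix(0, n, p)
    for (k in seq_len(params$n_datasets)) {
      drop_mask <- lapply(params$layers, function(h)
        matrix(stats::rbinom(n * h, 1L, 0.5) * 2, n, h))
      out <- forward(inp, drop_mask)[[nl + 1L]]
      xs_hat <- out[, seq_len(p), drop = FALSE]
      x_hat <- sweep(sweep(xs_hat, 2, sd, "*"), 2, mu, "+")
      acc <- acc + pmax(expm1(x_hat), 0)
    }
    imp <- acc / params$n_datasets
    v[missing] <- imp[missing]
    all_missing <- colSums(!missing) == 0L
    if (any(all_missing)) {
      prior <- stats::median(v[!missing], na.rm = TRUE)
      v[, all_missing] <- prior
    }
    v
  })
}

#' Size factors by median-of-ratios and library-size normalization
#'
#' `size_factors` computes DESeq-style median-of-ratios factors (the
#' per-sample median of count ratios to the per-feature geometric-mean
#' reference) and rescales them to geometric mean 1, a package convention
#' that fixes the global scale. `normalize_counts` divides each sample's
#' counts by its factor.
#'
#' @param m An [isomir_matrix()] in state `"imputed"`.
#' @return `size_factors`: numeric per-sample factors (geometric mean 1).
#' @export
size_factors <- function(m) {
  require_state(m, "imputed", "size_factors")
  v <- m$values
  ref <- apply(v, 2, function(col) if (all(col > 0)) exp(mean(log(col))) else 0)
  pos <- ref > 0
  if (!any(pos))
    stop_invalid("size factors need at least one feature with positive counts in every sample; none found")
  f <- vapply(seq_len(nrow(v)), function(i)
    stats::median(v[i, pos] / ref[pos]), 0)
  if (any(f <= 0))
    stop_invalid("non-positive size factor for sample(s) %s",
                 paste(which(f <= 0), collapse = ", "))
  f <- f / exp(mean(log(f)))
  names(f) <- rownames(m$values)
  f
}

#' @rdname size_factors
#' @param f Size factors from `size_factors`.
#' @return `normalize_counts`: `isomir_matrix` in state `"size-normalized"`.
#' @export
normalize_counts <- function(m, f = size_factors(m)) {
  require_state(m, "imputed", "normalize_counts")
  stopifnot(length(f) == nrow(m$values), all(f > 0))
  isomir_matrix(m$values / f, missing = m$missing, batch = m$batch,
                cohort = m$cohort, state = "size-normalized",
                medians = m$medians)
}

#' Restore original zeros after imputation
#'
#' Cells flagged in the missingness mask are set back to zero (imputed
#' values served only the size-factor computation); all other cells are
#' unchanged.
#'
#' @param m An [isomir_matrix()] in state `"imputed"` or
#'   `"size-normalized"`.
#' @return `isomir_matrix` with masked cells zeroed (state unchanged).
#' @export
restore_zeros <- function(m) {
  require_state(m, c("imputed", "size-normalized"), "restore_zeros")
  v <- m$values
  v[m$missing] <- 0
  isomir_matrix(v, missing = m$missing, batch = m$batch, cohort = m$cohort,
                state = m$state, medians = m$medians)
}

#' Batch adjustment (parametric empirical Bayes)
#'
#' Removes library-preparation batch effects with the parametric
#' empirical-Bayes location/scale model (ComBat), with no covariates beyond
#' the batch label. Features with zero variance are passed through
#' unchanged. Matrix shape and feature order are preserved.
#'
#' @param m An [isomir_matrix()] in state `"size-normalized"`.
#' @return `isomir_matrix` in state `"batch-adjusted"`.
#' @export
batch_adjust <- function(m) {
  require_state(m, "size-normalized", "batch_adjust")
  if (nlevels(droplevels(m$batch)) < 2L)
    stop_invalid("batch adjustment needs at least 2 batches")
  if (any(table(droplevels(m$batch)) < 2L))
    stop_invalid("every batch needs at least 2 samples")
  v <- t(m$values)  # features x samples
  varying <- apply(v, 1, stats::var) > 0
  adj <- v
  if (sum(varying) >= 2L) {
    quiet <- function(expr) suppressMessages(utils::capture.output(
      res <- expr, file = nullfile()))
    quiet(adj[varying, ] <- sva::ComBat(v[varying, , drop = FALSE],
                                        batch = droplevels(m$batch)))
  }
  isomir_matrix(t(adj), missing = m$missing, batch = m$batch,
                cohort = m$cohort, state = "batch-adjusted",
                medians = m$medians)
}

#' Intersect two cohorts' features and standardize per cohort
#'
#' Keeps the feature intersection of both matrices, stores each cohort's
#' per-feature medians on the pre-standardization scale (the scale used
#' later for dichotomization-threshold transfer), and z-scores every
#' feature within its cohort.
#'
#' @param m1,m2 [isomir_matrix()] objects in state `"batch-adjusted"`.
#' @return List of the two standardized matrices (state `"standardized"`,
#'   `medians` populated).
#' @export
intersect_and_standardize <- function(m1, m2) {
  require_state(m1, "batch-adjusted", "intersect_and_standardize")
  require_state(m2, "batch-adjusted", "intersect_and_standardize")
  shared <- intersect(colnames(m1$values), colnames(m2$values))
  if (!length(shared)) stop_invalid("no shared features between cohorts")
  std_one <- function(m) {
    v <- m$values[, shared, drop = FALSE]
    med <- apply(v, 2, stats::median)
    sd <- apply(v, 2, stats::sd)
    z <- scale(v)
    z[, sd == 0] <- 0
    z <- matrix(as.numeric(z), nrow(v), ncol(v), dimnames = dimnames(v))
    isomir_matrix(z, missing = m$missing[, shared, drop = FALSE],
                  batch = m$batch, cohort = m$cohort, state = "standardized",
                  medians = med)
  }
  list(std_one(m1), std_one(m2))
}

#' Run the full preprocessing chain on one cohort
#'
#' Convenience wrapper applying, in order: abundance filter, imputation,
#' size-factor normalization, zero restoration, and (when two or more
#' batches are present) batch adjustment.
#'
#' @param m An [isomir_matrix()] in state `"raw"`.
#' @param clinical Optional clinical table for the imputer.
#' @param min_mean Abundance threshold.
#' @param params [impute_params()].
#' @return `isomir_matrix` in state `"batch-adjusted"`.
#' @export
preprocess_cohort <- function(m, clinical = NULL, min_mean = 5,
                              params = impute_params()) {
  m <- abundance_filter(m, min_mean)
  m <- impute_missing(m, clinical, params)
  m <- restore_zeros(normalize_counts(m))
  if (nlevels(droplevels(m$batch)) >= 2L && all(table(droplevels(m$batch)) >= 2L)) {
    m <- batch_adjust(m)
  } else {
    m$state <- "batch-adjusted"
  }
  m
}
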