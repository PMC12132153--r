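mat_fixture <- function(values, batch = NULL, missing = NULL,
                        state = "raw") {
  v <- as.matrix(values)
  rownames(v) <- sprintf("s%02d", seq_len(nrow(v)))
  colnames(v) <- sprintf("f%02d", seq_len(ncol(v)))
  isomir_matrix(v, missing = missing, batch = batch, state = state)
}

test_that("abundance filter applies a strict mean-above-threshold rule", {
  v <- cbind(rep(1, 10), rep(5, 10), rep(5.1, 10), rep(10, 10))
  m <- mat_fixture(v)
  out <- abundance_filter(m)
  expect_identical(colnames(out$values), c("f03", "f04"))

  # planted means {1, 10}: exactly the 10-mean block survives
  set.seed(2)
  v2 <- cbind(matrix(rpois(100, 1), 10), matrix(rpois(100, 10), 10))
  out2 <- abundance_filter(mat_fixture(v2))
  expect_identical(colnames(out2$values), sprintf("f%02d", 11:20))

  expect_warning(abundance_filter(mat_fixture(matrix(0, 5, 3))), "every feature")
})

test_that("imputation fills only masked cells and honors both imputers", {
  v <- matrix(rpois(20, 15), 5, 4)
  m0 <- mat_fixture(v)
  expect_identical(impute_missing(m0)$values, m0$values)  # no missing: identity

  # median fallback on a 5x4 fixture, hand-computed medians
  v <- matrix(c(1, 2, 3, 4, 5,
                10, 20, NA, 40, 50,
                7, NA, NA, 7, 9,
                NA, NA, NA, NA, NA), 5, 4)
  m <- mat_fixture(v)
  out <- impute_missing(m, params = impute_params("median"))
  expect_equal(out$values[3, 2], 30)        # median of 10,20,40,50
  expect_equal(out$values[2, 3], 7)         # median of 7,7,9
  expect_equal(out$values[3, 3], 7)
  # fully missing feature gets the cohort prior (overall observed median)
  expect_equal(unique(out$values[, 4]), median(v[!is.na(v)]))
  # observed cells untouched
  expect_identical(out$values[!m$missing], m$values[!m$missing])
  expect_identical(out$state, "imputed")

  # DAE imputer: same contract, deterministic per seed
  set.seed(3)
  v2 <- matrix(rpois(200, 25), 20, 10) + 0
  miss <- matrix(runif(200) < 0.1, 20, 10)
  v2[miss] <- NA
  m2 <- mat_fixture(v2, missing = miss)
  pars <- impute_params("dae", layers = c(8, 4, 8), lr = 1e-3, passes = 15,
                        n_datasets = 4, seed = 11)
  o1 <- impute_missing(m2, params = pars)
  o2 <- impute_missing(m2, params = pars)
  expect_identical(o1$values, o2$values)
  expect_false(anyNA(o1$values))
  expect_true(all(o1$values >= 0))
  expect_identical(o1$values[!miss], m2$values[!miss])

  # defaults echo the imputation configuration
  dflt <- impute_params("dae")
  expect_identical(dflt$layers, c(512L, 512L, 512L))
  expect_equal(dflt$corruption, 0.95)
  expect_equal(dflt$lr, 1e-6)
  expect_identical(dflt$passes, 40L)
  expect_identical(dflt$n_datasets, 50L)
})

test_that("size factors are median-of-ratios with geometric mean 1", {
  set.seed(4)
  a <- rpois(30, 50) + 1
  m <- mat_fixture(rbind(a, 2 * a))
  m$state <- "imputed"
  f <- size_factors(m)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  norm <- normalize_counts(m, f)
  expect_equal(norm$values[1, ], norm$values[2, ], tolerance = 1e-12)

  single <- mat_fixture(matrix(a, 1))
  single$state <- "imputed"
  expect_equal(unname(size_factors(single)), 1)

  # independent literal median-of-ratios oracle on a random NB matrix
  v <- matrix(rnbinom(20 * 50, mu = 40, size = 2) + 1, 20, 50)
  mm <- mat_fixture(v); mm$state <- "imputed"
  got <- size_factors(mm)
  lit <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    ratios <- numeric(0)
    for (j in seq_len(ncol(v))) {
      g <- prod(v[, j])^(1 / nrow(v))
      if (g > 0) ratios <- c(ratios, v[i, j] / g)
    }
    lit[i] <- median(ratios)
  }
  lit <- lit / exp(mean(log(lit)))
  expect_equal(unname(got), lit, tolerance = 1e-10)
  # cross-check against the DESeq2 implementation (log-scale median;
  # agrees closely but not exactly for even feature counts)
  dsq <- DESeq2::estimateSizeFactorsForMatrix(t(v))
  dsq <- dsq / exp(mean(log(dsq)))
  expect_equal(unname(got), unname(dsq), tolerance = 0.02)

  # all-zero feature rows make the reference impossible
  bad <- mat_fixture(matrix(c(0, 1, 1, 0), 2, 2))
  bad$state <- "imputed"
  expect_error(size_factors(bad), "positive counts")
})

test_that("normalization is scale-equivariant in single-sample depth", {
  # multiplying one sample's counts by c changes that sample's factor by c
  # and no normalized profile, up to the global geometric-mean-1 constant
  # that the data-dependent reference absorbs
  set.seed(9)
  v <- matrix(rpois(15 * 20, 30) + 1, 15, 20)
  m <- mat_fixture(v); m$state <- "imputed"
  n1 <- normalize_counts(m)
  v2 <- v; v2[3, ] <- v2[3, ] * 5
  m2 <- mat_fixture(v2); m2$state <- "imputed"
  n2 <- normalize_counts(m2)
  f1 <- size_factors(m); f2 <- size_factors(m2)
  expect_equal(unname((f2[3] / f1[3]) / (f2[1] / f1[1])), 5,
               tolerance = 1e-10)
  ratio <- n2$values / n1$values
  expect_lt(diff(range(ratio)), 1e-10)  # profiles unchanged up to a constant
})

test_that("restoring zeros rewrites exactly the masked cells", {
  v <- matrix(rpois(24, 10) + 1, 6, 4)
  m <- mat_fixture(v); m$state <- "imputed"
  expect_identical(restore_zeros(m)$values, m$values)  # all-false mask

  miss <- matrix(FALSE, 6, 4); miss[cbind(c(1, 3, 5), c(2, 4, 1))] <- TRUE
  m2 <- mat_fixture(v, missing = miss); m2$state <- "size-normalized"
  out <- restore_zeros(m2)
  expect_true(all(out$values[miss] == 0))
  expect_identical(out$values[!miss], v[!miss])

  m3 <- mat_fixture(v, missing = matrix(TRUE, 6, 4)); m3$state <- "imputed"
  expect_true(all(restore_zeros(m3)$values == 0))
})

test_that("batch adjustment is near-identity without batch effects and shrinks planted ones", {
  set.seed(12)
  half <- matrix(rnorm(20 * 30, 10, 2), 20, 30)
  dup <- mat_fixture(rbind(half, half), batch = rep(c("b1", "b2"), each = 20))
  dup$state <- "size-normalized"
  out <- batch_adjust(dup)
  # with no batch effect the adjustment is close to the identity (residual
  # empirical-Bayes scale shrinkage stays well under the data's spread)
  expect_lt(max(abs(out$values - dup$values)), 0.1 * sd(dup$values))
  expect_identical(dim(out$values), dim(dup$values))
  expect_identical(colnames(out$values), colnames(dup$values))

  # planted additive shift delta = 3 on half the samples: the systematic
  # batch-mean difference collapses (per-feature sampling noise remains)
  delta <- 3
  v <- matrix(rnorm(40 * 25, 10, 2), 40, 25)
  v[21:40, ] <- v[21:40, ] + delta
  m <- mat_fixture(v, batch = rep(c("b1", "b2"), each = 20))
  m$state <- "size-normalized"
  adj <- batch_adjust(m)$values
  shift <- mean(colMeans(adj[21:40, ]) - colMeans(adj[1:20, ]))
  expect_lt(abs(shift), 0.2 * delta)

  # planted variance ratio of 4 is equalized
  v2 <- rbind(matrix(rnorm(20 * 25, 10, 1), 20, 25),
              matrix(rnorm(20 * 25, 10, 2), 20, 25))
  m2 <- mat_fixture(v2, batch = rep(c("b1", "b2"), each = 20))
  m2$state <- "size-normalized"
  adj2 <- batch_adjust(m2)$values
  vr <- apply(adj2[21:40, ], 2, var) / apply(adj2[1:20, ], 2, var)
  expect_gt(mean(vr), 0.8)
  expect_lt(mean(vr), 1.25)

  # a single-sample batch is refused
  m3 <- mat_fixture(v[1:5, ], batch = c("b1", "b1", "b1", "b1", "b2"))
  m3$state <- "size-normalized"
  expect_error(batch_adjust(m3), "at least 2 samples")
})

test_that("cohort intersection standardizes shared features and keeps medians", {
  set.seed(14)
  v <- matrix(rnorm(20 * 10, 50, 8), 20, 10)
  m1 <- mat_fixture(v); m1$state <- "batch-adjusted"
  m2 <- mat_fixture(v); m2$state <- "batch-adjusted"
  std <- intersect_and_standardize(m1, m2)
  expect_identical(std[[1]]$values, std[[2]]$values)
  expect_lt(max(abs(colMeans(std[[1]]$values))), 1e-12)
  expect_equal(unname(apply(std[[1]]$values, 2, sd)), rep(1, 10))
  expect_equal(unname(std[[1]]$medians), unname(apply(v, 2, median)))
  expect_identical(std[[1]]$state, "standardized")

  m3 <- mat_fixture(v[, 1:3]); m3$state <- "batch-adjusted"
  colnames(m3$values) <- paste0("other", 1:3)
  colnames(m3$missing) <- colnames(m3$values)
  expect_error(intersect_and_standardize(m1, m3), "no shared")
})

test_that("the pipeline state machine refuses out-of-order calls", {
  v <- matrix(rpois(40, 20) + 1, 10, 4)
  raw <- mat_fixture(v)
  expect_error(size_factors(raw), "state")
  expect_error(batch_adjust(raw), "state")
  expect_error(restore_zeros(raw), "state")
  expect_error(intersect_and_standardize(raw, raw), "state")
  imputed <- impute_missing(raw)
  expect_error(impute_missing(imputed), "state")
  expect_error(abundance_filter(imputed), "state")
})
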