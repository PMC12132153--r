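test_that("Kaplan-Meier estimates match a hand product-limit table", {
  # 10 patients, events at 1,2,4,6,7,9; censored at 3,5,8,10
  times <- 1:10
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- km_estimate(times, events)
  s <- km$surv[match(c(1, 2, 4, 6, 7, 9), km$time)]
  expect_equal(s, c(9 / 10, 8 / 10, 24 / 35, 96 / 175, 72 / 175, 36 / 175),
               tolerance = 1e-12)
  expect_equal(km$median, 7)  # first time S(t) <= 0.5
  expect_equal(km$fun(6.5), 96 / 175)

  # no censoring, distinct times: steps of 1/n
  km2 <- km_estimate(1:5, rep(1, 5))
  expect_equal(km2$surv, seq(0.8, 0, by = -0.2))

  # all censored: flat curve, undefined median
  km3 <- km_estimate(1:5, rep(0, 5))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank agrees with the explicit O-E oracle and is label-symmetric", {
  times <- c(2, 4, 5, 7, 8, 11, 12, 15)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  lr <- logrank_test(times, events, group)
  expect_equal(lr$chisq, oracle_logrank(times, events, group),
               tolerance = 1e-10)
  flipped <- logrank_test(times, events, ifelse(group == "a", "b", "a"))
  expect_equal(lr$chisq, flipped$chisq, tolerance = 1e-12)

  # identical groups: statistic 0
  t2 <- rep(c(1, 3, 6, 9), 2); e2 <- rep(1, 8)
  g2 <- rep(c("x", "y"), each = 4)
  expect_lt(logrank_test(t2, e2, g2)$chisq, 1e-10)

  expect_error(logrank_test(times, events, rep("a", 8)), "two")
})

test_that("Cox fits solve the analytic two-event partial likelihood", {
  # patients (t, e, x): (1,1,1), (2,1,0), (3,0,1), (4,0,0)
  # d/dbeta log PL = 0  =>  exp(beta) = sqrt(2)
  f <- cox_fit(data.frame(x = c(1, 0, 1, 0)), times = 1:4,
               events = c(1, 1, 0, 0))
  expect_equal(f$table$beta, log(sqrt(2)), tolerance = 1e-7)
  expect_true(f$table$ci_lower < f$table$hr && f$table$hr < f$table$ci_upper)
  expect_true(f$cindex >= 0 && f$cindex <= 1)

  # null covariate at large n: HR near 1
  set.seed(5)
  s <- sim_surv_binary(1500, log_hr = 0)
  fn <- cox_fit(data.frame(x = s$x), s$time, s$event)
  expect_lt(abs(fn$table$beta), 3 * fn$table$se)

  expect_error(cox_fit(data.frame(x = rep(1, 10)), rexp(10), rbinom(10, 1, 1)),
               "constant")
  expect_error(cox_fit(data.frame(x = rnorm(10)), rexp(10), rep(0, 10)),
               "event")
})

test_that("Cox score test matches the log-rank statistic on tie-free data", {
  set.seed(6)
  s <- sim_surv_binary(80, log_hr = 0.7)
  expect_identical(anyDuplicated(s$time), 0L)
  f <- cox_fit(data.frame(x = s$x), s$time, s$event)
  lr <- logrank_test(s$time, s$event, s$x)
  expect_equal(unname(f$fit$score), unname(lr$chisq), tolerance = 1e-6)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(rep(1, 7)), rep(1, 7))
  expect_equal(bh_fdr(0.034), 0.034)
  p10 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.368)
  expect_equal(bh_fdr(p10), oracle_bh(p10), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("time-dependent AUC is exact for perfect ranking, null for noise, and matches brute force", {
  set.seed(8)
  t <- rexp(60); e <- rep(1, 60)
  perfect <- suppressWarnings(cumulative_dynamic_auc(-t, t, e))
  expect_true(all(perfect$auc == 1))

  null_auc <- replicate(20, {
    t <- rexp(100); e <- rbinom(100, 1, 0.8)
    suppressWarnings(cumulative_dynamic_auc(rnorm(100), t, e))$mean_auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)

  for (i in 1:10) {
    n <- sample(15:30, 1)
    t <- round(rexp(n, 0.1), 1) + 0.1
    e <- rbinom(n, 1, 0.7)
    if (sum(e) < 2) next
    r <- rnorm(n)
    grid <- sort(unique(t[e == 1]))
    grid <- grid[grid < max(t)]
    if (!length(grid)) next
    got <- suppressWarnings(cumulative_dynamic_auc(r, t, e, grid))
    want <- vapply(got$times, function(u) oracle_auc_at(r, t, e, u), 0)
    expect_equal(got$auc, want, tolerance = 1e-10)
  }

  set.seed(81)
  expect_warning(cumulative_dynamic_auc(rnorm(20), rexp(20) + 1,
                                        rbinom(20, 1, 0.9), c(2, 1e6)),
                 "beyond last")
})

test_that("C-index is invariant to strictly increasing transforms of risk", {
  set.seed(9)
  r <- rnorm(100); t <- rexp(100, exp(0.5 * r)); e <- rbinom(100, 1, 0.8)
  c1 <- cindex(r, t, e)
  expect_equal(cindex(exp(r), t, e), c1, tolerance = 1e-12)
  expect_equal(cindex(100 + 3 * r, t, e), c1, tolerance = 1e-12)
  # internal fast concordance agrees with the survival-package route
  expect_equal(isomiRSurv:::harrell_cindex_fast(r, t, e), c1,
               tolerance = 1e-12)
})

test_that("dichotomization follows the >=-median rule and transfers thresholds", {
  v <- c(3, 9, 1, 7, 5, 11, 13)  # odd n, distinct: median 7
  d <- dichotomize(v)
  expect_identical(sum(d$high), 4L)  # (n + 1) / 2 values >= median
  expect_equal(d$rule$threshold, 7)

  # transferred rule applied as-is (threshold 246, high = ">= 246")
  rule <- structure(list(threshold = 246, orientation = ">=",
                         source = "discovery"),
                    class = "dichotomization_rule")
  out <- dichotomize(c(100, 246, 300, 245.9), rule)
  expect_identical(out$high, c(0L, 1L, 1L, 0L))
  expect_equal(out$rule$threshold, 246)

  set.seed(10)
  x <- rnorm(101)
  expect_identical(dichotomize(x)$high, as.integer(x >= median(x)))
  expect_error(dichotomize(rep(2, 5)), "identical")
})

test_that("cutpoint optimization recovers a planted split and guards arm sizes", {
  set.seed(11)
  v <- c(rnorm(80, 5, 1), rnorm(80, 10, 1))
  t <- rexp(160, 0.05 * exp(-1.2 * (v > 7.5)))
  r <- optimize_cutpoint(v, t, rep(1, 160))
  expect_lt(abs(r$threshold - 7.5), 1)
  expect_lt(attr(r, "log_hr"), 0)

  expect_error(optimize_cutpoint(rep(4, 50), rexp(50), rep(1, 50)),
               "no admissible")

  # monotone linear hazard: the guard keeps the split off the extremes
  v2 <- seq_len(100)
  t2 <- rexp(100, 0.05 * exp(0.02 * v2))
  r2 <- optimize_cutpoint(v2, t2, rep(1, 100))
  expect_gte(r2$threshold, sort(v2)[10])
  expect_lte(r2$threshold, sort(v2)[91])
})

test_that("ratio biomarkers divide elementwise and refuse zero denominators", {
  a <- c(2, 4, 6)
  expect_equal(ratio_biomarker(a, a), rep(1, 3))
  expect_equal(ratio_biomarker(3 * a, a), rep(3, 3))
  expect_equal(ratio_biomarker(c(264, 150), c(70, 50)), c(264 / 70, 3))
  expect_error(ratio_biomarker(a, c(1, 0, 2)), "sample\\(s\\): 2")
})

test_that("the PH check is calibrated under PH and powered against drifting effects", {
  set.seed(12)
  null_p <- replicate(20, {
    s <- sim_surv_binary(300, log_hr = 0.5)
    f <- cox_fit(data.frame(x = s$x), s$time, s$event)
    unname(ph_check(f)["x"])
  })
  expect_lte(mean(null_p < 0.05), 0.25)

  # beta(t) = b0 * t: inverse-transform simulation of the drifting effect
  drift_p <- replicate(15, {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    u <- rexp(n)
    b0 <- 0.2; lam <- 0.08
    t <- ifelse(x == 0, u / lam, log(1 + b0 * u / lam) / b0)
    f <- cox_fit(data.frame(x = x), t, rep(1, n))
    unname(ph_check(f)["x"])
  })
  expect_gte(mean(drift_p < 0.05), 0.8)
})
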