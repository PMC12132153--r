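#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. The preset
#' constructors [discovery_config()] and [replication_config()] encode the
#' study conditions this generator emulates: a discovery cohort of 154
#' patients with ~9% censoring and a replication cohort of 200 patients with
#' ~54% censoring, sequenced in library batches of at most 48 samples,
#' negative-binomially distributed UMI counts, and a planted prognostic
#' isomiR (hazard ratio 0.6, dichotomous above the cohort median).
#'
#' The random-censoring rate that realizes a target censoring fraction q
#' under an exponential event-time model with baseline hazard h is
#' `h * q / (1 - q)` (competing exponentials); [censoring_rate_for_target()]
#' exposes that closed form.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of isomiR features.
#' @param planted List of planted prognostic effects, each
#'   `list(feature = <name or index>, hr = <hazard ratio>, mechanism =
#'   "dichotomous"|"linear")`. Dichotomous effects multiply the hazard by
#'   `hr` for patients whose latent count exceeds the cohort median; linear
#'   effects multiply it by `hr^z` where z is the standardized log1p count.
#' @param baseline_hazard Baseline event rate per month.
#' @param censoring `list(admin_time, random_rate)`: administrative
#'   censoring time (months, may be `Inf`) and random-censoring rate. A
#'   `target` entry (fraction in (0, 1)) replaces `random_rate` by the rate
#'   solving `E[c / (c + h_i)] = target` over the realized per-patient
#'   hazards, so the expected censoring fraction matches the target even
#'   under planted-effect heterogeneity.
#' @param batch_sizes Integer vector of library batch sizes (each <= 48,
#'   summing to `n_patients`).
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param mean_log_umi Mean of the log feature-abundance distribution.
#' @param missing_rate Missing-completely-at-random dropout rate in [0, 1).
#' @param clinical Named list of clinical marginal parameters (see
#'   [discovery_config()] for the discovery-cohort values).
#' @param clinical_effects Named log-hazard-ratios per standard deviation
#'   for prognostic clinical markers (`log_nfl`, `delta_frs`, `log_mir181`).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients, n_features = 1480L,
                          planted = list(),
                          baseline_hazard = log(2) / 14,
                          censoring = list(admin_time = Inf,
                                           random_rate = 0),
                          batch_sizes = NULL,
                          nb_dispersion = 0.4,
                          mean_log_umi = log(20),
                          missing_rate = 0.05,
                          clinical = clinical_marginals_discovery(),
                          clinical_effects = c(log_nfl = log(1.6),
                                               delta_frs = log(1.25),
                                               log_mir181 = log(1.4)),
                          seed = 1L) {
  if (is.null(batch_sizes)) {
    nb <- ceiling(n_patients / 48)
    batch_sizes <- rep(48L, nb)
    batch_sizes[nb] <- n_patients - 48L * (nb - 1L)
  }
  if (sum(batch_sizes) != n_patients)
    stop_invalid("batch_sizes must sum to n_patients (%d != %d)",
                 sum(batch_sizes), n_patients)
  if (any(batch_sizes > 48L))
    stop_invalid("each library batch holds at most 48 samples")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must be in [0, 1)")
  for (p in planted) {
    if (is.null(p$hr) || p$hr <= 0) stop_invalid("planted hazard_ratio must be > 0")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features), planted = planted,
                 baseline_hazard = baseline_hazard, censoring = censoring,
                 batch_sizes = as.integer(batch_sizes),
                 nb_dispersion = nb_dispersion, mean_log_umi = mean_log_umi,
                 missing_rate = missing_rate, clinical = clinical,
                 clinical_effects = clinical_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param target Target censoring fraction in (0, 1).
#' @export
censoring_rate_for_target <- function(target, baseline_hazard) {
  stopifnot(target > 0, target < 1)
  baseline_hazard * target / (1 - target)
}

# Clinical marginal parameters matching the two cohorts' demographic tables.
clinical_marginals_discovery <- function() {
  list(sex_m = 0.59, age_onset = c(62.3, 11), age_enroll = c(63.9, 11),
       alsfrs = c(38, 7), delta_meanlog = log(0.6), delta_sdlog = 0.81,
       bulbar = 0.34, riluzole = 0.71,
       nfl_meanlog = log(70), nfl_sdlog = 0.7,
       mir181_meanlog = log(5e4), mir181_sdlog = 0.8)
}

clinical_marginals_replication <- function() {
  list(sex_m = 0.45, age_onset = c(57, 12), age_enroll = c(53.4, 12),
       alsfrs = c(39, 6), delta_meanlog = log(0.6), delta_sdlog = 0.6,
       bulbar = 0.28, riluzole = 0.67,
       nfl_meanlog = log(70), nfl_sdlog = 0.7,
       mir181_meanlog = log(5e4), mir181_sdlog = 0.8)
}

# Element-wise preset overrides (no recursive merging; NULL values are
# passed through to cohort_config explicitly).
apply_overrides <- function(args, override) {
  for (nm in names(override)) args[nm] <- list(override[[nm]])
  args
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @export
discovery_config <- function(n_features = 1480L, seed = 101L, ...) {
  h <- log(2) / 13.9
  args <- list(n_patients = 154L, n_features = n_features,
               planted = list(list(feature = "isomiR-letA-5p.t", hr = 0.6,
                                   mechanism = "dichotomous")),
               baseline_hazard = h,
               censoring = list(admin_time = Inf, target = 0.09),
               clinical = clinical_marginals_discovery(), seed = seed)
  do.call(cohort_config, apply_overrides(args, list(...)))
}

#' @rdname cohort_config
#' @export
replication_config <- function(n_features = 1480L, seed = 202L, ...) {
  h <- log(2) / 14.7
  args <- list(n_patients = 200L, n_features = n_features,
               planted = list(list(feature = "isomiR-letA-5p.t", hr = 0.6,
                                   mechanism = "dichotomous")),
               baseline_hazard = h,
               censoring = list(admin_time = Inf, target = 0.54),
               clinical = clinical_marginals_replication(), seed = seed)
  do.call(cohort_config, apply_overrides(args, list(...)))
}

#' Shared isomiR feature catalog
#'
#' Builds the feature universe shared by both simulated cohorts: miRNA genes
#' (including a near-identical "letA/letB/letC" family) each carrying one to
#' four isomiR variants named through the canonical nomenclature, with
#' log-normally distributed baseline mean abundances. The planted marker
#' `isomiR-letA-5p.t` is always present with a baseline mean of 264 UMIs
#' (matching the reported abundance scale of the headline marker).
#'
#' @param n_features Total number of isomiR features.
#' @param seed Integer seed.
#' @param mean_log_umi Mean log abundance for the log-normal feature means.
#' @return Data frame `feature`, `gene`, `base_mean`.
#' @export
make_feature_catalog <- function(n_features, seed = 1L,
                                 mean_log_umi = log(20)) {
  stopifnot(n_features >= 2)
  with_seed(seed, {
    variants <- c("", ".t", ".tt", ".a", ".c", ".as")
    genes <- c("letA-5p", "letB-5p", "letC-5p",
               paste0("mir", seq_len(max(1, n_features)), "-",
                      sample(c("5p", "3p"), max(1, n_features), replace = TRUE)))
    feats <- character(0); gmap <- character(0)
    gi <- 1L
    while (length(feats) < n_features) {
      g <- genes[gi]
      k <- sample(1:4, 1L)
      vs <- c("", sample(variants[-1], k - 1L))
      nm <- paste0("isomiR-", g, vs)
      take <- min(length(nm), n_features - length(feats))
      feats <- c(feats, nm[seq_len(take)])
      gmap <- c(gmap, rep(g, take))
      gi <- gi + 1L
    }
    marker <- "isomiR-letA-5p.t"
    if (!marker %in% feats) {
      feats[2L] <- marker
      gmap[2L] <- "letA-5p"
    }
    base_mean <- exp(stats::rnorm(n_features, mean_log_umi, 1.3))
    base_mean[feats == marker] <- 264
    data.frame(feature = feats, gene = gmap, base_mean = base_mean,
               stringsAsFactors = FALSE)
  })
}

resolve_planted <- function(planted, catalog) {
  lapply(planted, function(p) {
    f <- p$feature
    if (is.numeric(f)) {
      if (f < 1 || f > nrow(catalog))
        stop_invalid("planted feature index %s outside [1, %d]",
                     format(f), nrow(catalog))
      p$feature <- catalog$feature[f]
    } else if (!f %in% catalog$feature) {
      stop_invalid("planted feature '%s' not in catalog", f)
    }
    p$mechanism <- match.arg(p$mechanism %||% "dichotomous",
                             c("dichotomous", "linear"))
    p
  })
}

#' Simulate one cohort (counts + survival)
#'
#' Counts are negative binomial per feature around the catalog baseline
#' mean, scaled by a per-sample library depth (log-normal, sd 0.3) and a
#' per-batch multiplicative effect (log-normal, sd 0.15); dropout is
#' missing-completely-at-random. Survival times are exponential under a
#' proportional-hazards model whose linear predictor collects the planted
#' isomiR effects (acting on latent, pre-dropout counts) and mild prognostic
#' contributions from NfL, DeltaFRS, and miR-181; censoring is the minimum
#' of an administrative cutoff and an exponential random-censoring time.
#'
#' @param cfg A [cohort_config()].
#' @param catalog Feature catalog from [make_feature_catalog()].
#' @param cohort_label Cohort label stored in the count matrix.
#' @return List `counts` (an [isomir_matrix()] in state `"raw"`),
#'   `clinical` (survival table), and `truth` (planted effects, linear
#'   predictor, latent counts).
#' @export
simulate_cohort <- function(cfg, catalog, cohort_label = "cohort") {
  stopifnot(inherits(cfg, "cohort_config"))
  if (nrow(catalog) != cfg$n_features)
    stop_invalid("catalog has %d features but config expects %d",
                 nrow(catalog), cfg$n_features)
  planted <- resolve_planted(cfg$planted, catalog)
  with_seed(cfg$seed, {
    n <- cfg$n_patients; p <- cfg$n_features
    batch <- factor(rep(seq_along(cfg$batch_sizes), cfg$batch_sizes))
    batch_mult <- exp(stats::rnorm(nlevels(batch), 0, 0.15))[batch]
    depth <- exp(stats::rnorm(n, 0, 0.3))
    mu <- outer(depth * batch_mult, catalog$base_mean)
    latent <- matrix(stats::rnbinom(n * p, mu = mu,
                                    size = 1 / cfg$nb_dispersion), n, p)
    colnames(latent) <- catalog$feature
    rownames(latent) <- sprintf("%s_p%03d", cohort_label, seq_len(n))

    # clinical covariates (independent marginals)
    cl <- cfg$clinical
    sex <- ifelse(stats::runif(n) < cl$sex_m, "M", "F")
    age_onset <- stats::rnorm(n, cl$age_onset[1], cl$age_onset[2])
    age_enroll <- stats::rnorm(n, cl$age_enroll[1], cl$age_enroll[2])
    alsfrs <- pmin(48, pmax(0, round(stats::rnorm(n, cl$alsfrs[1],
                                                  cl$alsfrs[2]))))
    delta_frs <- exp(stats::rnorm(n, cl$delta_meanlog, cl$delta_sdlog))
    onset_site <- ifelse(stats::runif(n) < cl$bulbar, "bulbar", "non-bulbar")
    riluzole <- ifelse(stats::runif(n) < cl$riluzole, "yes", "no")
    nfl <- exp(stats::rnorm(n, cl$nfl_meanlog, cl$nfl_sdlog))
    mir181 <- exp(stats::rnorm(n, cl$mir181_meanlog, cl$mir181_sdlog))

    # linear predictor: planted isomiR effects act on latent counts
    eta <- rep(0, n)
    for (pl in planted) {
      x <- latent[, pl$feature]
      if (pl$mechanism == "dichotomous") {
        eta <- eta + log(pl$hr) * (x > stats::median(x))
      } else {
        z <- as.vector(scale(log1p(x)))
        eta <- eta + log(pl$hr) * z
      }
    }
    ce <- cfg$clinical_effects
    ce_get <- function(nm) if (!is.null(ce) && nm %in% names(ce)) ce[[nm]] else 0
    zsc <- function(v) as.vector(scale(v))
    eta <- eta +
      ce_get("log_nfl") * zsc(log(nfl)) +
      ce_get("delta_frs") * zsc(delta_frs) +
      ce_get("log_mir181") * zsc(log(mir181))

    hazards <- cfg$baseline_hazard * exp(eta)
    t_event <- stats::rexp(n, rate = hazards)
    c_rate <- cfg$censoring$random_rate %||% 0
    if (!is.null(cfg$censoring$target)) {
      # solve E[c / (c + h_i)] = target over the realized hazards, so the
      # censoring fraction hits its target under effect heterogeneity
      q <- cfg$censoring$target
      c_rate <- stats::uniroot(
        function(c) mean(c / (c + hazards)) - q,
        lower = 1e-8, upper = max(hazards) * q / (1 - q) * 10 + 1)$root
    }
    c_rand <- if (c_rate > 0) stats::rexp(n, c_rate) else rep(Inf, n)
    c_all <- pmin(c_rand, cfg$censoring$admin_time %||% Inf)
    time <- pmin(t_event, c_all)
    event <- as.integer(t_event <= c_all)

    values <- latent
    missing <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    values[missing] <- NA_real_

    clinical <- data.frame(
      patient_id = rownames(latent), time = time, event = event,
      age_onset = age_onset, age_enroll = age_enroll, sex = sex,
      onset_site = onset_site, riluzole = riluzole, alsfrs_r = alsfrs,
      delta_frs = delta_frs, nfl = nfl, mir181 = mir181,
      stringsAsFactors = FALSE)

    list(counts = isomir_matrix(values, missing = missing, batch = batch,
                                cohort = cohort_label, state = "raw"),
         clinical = clinical,
         truth = list(planted = planted, eta = eta, latent = latent))
  })
}

#' Simulate the discovery and replication cohorts
#'
#' Both cohorts share one feature catalog (derived from `catalog_seed`), so
#' feature identities agree across cohorts while counts, clinical data, and
#' survival are drawn independently per cohort configuration.
#'
#' @param cfg_discovery,cfg_replication [cohort_config()] objects with equal
#'   `n_features`.
#' @param catalog_seed Seed for the shared catalog (default: derived from
#'   the discovery seed).
#' @return List with elements `discovery`, `replication` (each as returned
#'   by [simulate_cohort()]) and `catalog`.
#' @export
simulate_cohorts <- function(cfg_discovery, cfg_replication,
                             catalog_seed = NULL) {
  if (cfg_discovery$n_features != cfg_replication$n_features)
    stop_invalid("cohorts must share the feature universe")
  catalog_seed <- catalog_seed %||% derive_seed(cfg_discovery$seed, 7L)
  catalog <- make_feature_catalog(cfg_discovery$n_features, catalog_seed,
                                  cfg_discovery$mean_log_umi)
  list(discovery = simulate_cohort(cfg_discovery, catalog, "discovery"),
       replication = simulate_cohort(cfg_replication, catalog, "replication"),
       catalog = catalog)
}

#' Write a cohort configuration as YAML / read it back
#'
#' @param cfg A [cohort_config()].
#' @param path YAML path.
#' @export
write_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$clinical_effects <- as.list(x$clinical_effects)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$clinical_effects <- unlist(x$clinical_effects)
  do.call(cohort_config, x)
}
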