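test_that("reference panels are valid, deterministic, and contain a near-identical family", {
  expect_error(make_reference(0), "positive integer")

  p1 <- make_reference(1, seed = 0)
  expect_identical(nrow(p1), 1L)
  expect_true(nchar(p1$mature_seq) >= 18 && nchar(p1$mature_seq) <= 25)

  a <- make_reference(50, seed = 7)
  b <- make_reference(50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_reference(50, seed = 8)))

  # brute-force Hamming scan finds at least one pair at distance <= 2
  ham <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    if (length(cx) != length(cy)) return(Inf)
    sum(cx != cy)
  }
  close_pairs <- 0L
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq.int(i + 1, nrow(a))) {
      if (ham(a$mature_seq[i], a$mature_seq[j]) <= 2) close_pairs <- close_pairs + 1L
    }
  }
  expect_gte(close_pairs, 1L)
})

test_that("reference FASTA round-trips through Biostrings", {
  p <- make_reference(8, seed = 3)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(p, path)
  back <- read_reference_fasta(path)
  expect_identical(back$gene_id, p$gene_id)
  expect_identical(back$mature_seq, toupper(p$mature_seq))
})

test_that("simulated reads follow the documented layout and conserve profile draws", {
  panel <- make_reference(6, seed = 2)
  prof <- c("isomiR-letA-5p" = 3, "isomiR-letA-5p.t" = 1,
            "isomiR-letB-5p.a" = 1)
  expect_error(simulate_reads(panel, numeric(0), 10), "non-empty")

  empty <- simulate_reads(panel, prof, 0, seed = 1)
  expect_identical(nrow(empty$reads), 0L)

  sim <- simulate_reads(panel, prof, 300, seed = 11)
  expect_identical(nrow(sim$reads), 300L)
  # adapter present in every read (independent substring scan)
  expect_true(all(grepl("TGGAATTCTCGGGTGCCAAGG", sim$reads$seq, fixed = TRUE)))
  # conservation: ground-truth label counts are a single multinomial draw
  expect_identical(sum(table(sim$truth$feature)), 300L)
  # single-feature profile puts that insert in every read
  one <- simulate_reads(panel, c("isomiR-letA-5p" = 1), 40, seed = 4)
  ins <- isomir_seq("isomiR-letA-5p", panel)
  expect_true(all(startsWith(one$reads$seq, ins)))
  # determinism
  expect_identical(simulate_reads(panel, prof, 50, seed = 9),
                   simulate_reads(panel, prof, 50, seed = 9))
})

test_that("FASTQ round-trips with qualities", {
  panel <- make_reference(4, seed = 1)
  sim <- simulate_reads(panel, c("isomiR-letA-5p" = 1), 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_identical(back$seq, sim$reads$seq)
  expect_identical(back$qual, sim$reads$qual)
})

test_that("cohort generator hits its censoring targets and is deterministic", {
  cfg_d <- discovery_config(n_features = 30, seed = 5)
  cfg_r <- replication_config(n_features = 30, seed = 6)
  sim <- simulate_cohorts(cfg_d, cfg_r)
  expect_identical(colnames(sim$discovery$counts$values),
                   colnames(sim$replication$counts$values))
  expect_identical(nrow(sim$discovery$counts$values), 154L)
  expect_identical(nrow(sim$replication$counts$values), 200L)
  # censoring fractions near the 9% / 54% targets (binomial noise band)
  cens <- replicate(5, {
    s <- simulate_cohorts(discovery_config(n_features = 30,
                                           seed = sample.int(1e6, 1)),
                          replication_config(n_features = 30,
                                             seed = sample.int(1e6, 1)))
    c(mean(1 - s$discovery$clinical$event),
      mean(1 - s$replication$clinical$event))
  })
  expect_lt(abs(mean(cens[1, ]) - 0.09), 0.05)
  expect_lt(abs(mean(cens[2, ]) - 0.54), 0.06)
  # batch structure respects the <= 48 kit constraint
  expect_true(all(table(sim$discovery$counts$batch) <= 48))
  expect_identical(simulate_cohorts(cfg_d, cfg_r), sim)
  # invalid planted index
  expect_error(simulate_cohort(
    cohort_config(50, n_features = 10,
                  planted = list(list(feature = 99, hr = 2,
                                      mechanism = "linear"))),
    make_feature_catalog(10, 1)), "outside")
})

test_that("null cohorts carry no systematic feature effect", {
  set.seed(31)
  betas <- replicate(10, {
    cfg <- cohort_config(n_patients = 120, n_features = 6,
                         planted = list(), missing_rate = 0,
                         clinical_effects = NULL,
                         seed = sample.int(1e6, 1))
    co <- simulate_cohort(cfg, make_feature_catalog(6, sample.int(1e6, 1)))
    x <- co$counts$values[, 3]
    hi <- as.numeric(x > median(x))
    if (length(unique(hi)) < 2) return(NA_real_)
    f <- cox_fit(data.frame(hi = hi), co$clinical$time, co$clinical$event)
    f$table$beta
  })
  expect_lt(abs(mean(betas, na.rm = TRUE)), 0.15)
})

test_that("planted log-hazard ratios are recovered within 3 standard errors", {
  # parameter recovery across HR in {0.5, 0.6, 2.0}, ~100 replicates total
  set.seed(77)
  hrs <- c(0.5, 0.6, 2.0)
  ok <- 0L; total <- 0L
  for (hr in hrs) {
    for (r in 1:34) {
      cfg <- cohort_config(n_patients = 1000, n_features = 4,
                           planted = list(list(feature = 2, hr = hr,
                                               mechanism = "dichotomous")),
                           missing_rate = 0, clinical_effects = NULL,
                           seed = sample.int(1e6, 1))
      co <- simulate_cohort(cfg, make_feature_catalog(4, sample.int(1e6, 1)))
      x <- co$counts$values[, 2]
      hi <- as.numeric(x > median(x))
      f <- cox_fit(data.frame(hi = hi), co$clinical$time, co$clinical$event)
      total <- total + 1L
      if (abs(f$table$beta - log(hr)) <= 3 * f$table$se) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("cohort configs validate and round-trip through YAML", {
  expect_error(cohort_config(100, batch_sizes = c(50, 50)), "at most 48")
  expect_error(cohort_config(100, batch_sizes = c(48, 48)), "sum")
  expect_error(cohort_config(100, missing_rate = 1), "missing_rate")
  expect_error(cohort_config(100, planted = list(list(feature = 1, hr = -2,
                                                      mechanism = "linear"))),
               "hazard_ratio")
  cfg <- cohort_config(96, n_features = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_identical(back$n_patients, cfg$n_patients)
  expect_identical(back$batch_sizes, cfg$batch_sizes)
  expect_equal(back$clinical_effects, cfg$clinical_effects,
               tolerance = 1e-9)
})
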