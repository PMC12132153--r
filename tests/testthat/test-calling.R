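test_that("quality trimming keeps clean reads, rejects bad ones, and is error-monotone", {
  full <- quality_trim(rep(40L, 30))
  expect_true(full$keep)
  expect_identical(c(full$start, full$end), c(1L, 30L))

  expect_false(quality_trim(rep(2L, 30))$keep)
  expect_false(quality_trim(integer(0))$keep)
  expect_error(quality_trim(rep(30L, 5), threshold = 0), "threshold")

  # raising the error tolerance can only extend the kept region
  set.seed(8)
  for (i in 1:50) {
    q <- random_qual(40)
    lo <- quality_trim(q, 0.02)
    hi <- quality_trim(q, 0.2)
    if (lo$keep) {
      expect_true(hi$keep)
      expect_lte(hi$start, lo$start)
      expect_gte(hi$end, lo$end)
    }
  }
})

test_that("quality trimming equals the literal running-sum rule on random reads", {
  set.seed(101)
  for (i in 1:200) {
    q <- random_qual(60, lo = 0L, hi = 20L)
    expect_identical(quality_trim(q), oracle_quality_trim(q))
  }
})

test_that("ambiguity trimming returns the longest <=2-N window, leftmost on ties", {
  w <- ambiguity_trim("ACGTACGT")
  expect_identical(c(w$start, w$end), c(1L, 8L))
  w <- ambiguity_trim("NNNNN")
  expect_identical(c(w$start, w$end), c(1L, 2L))
  set.seed(5)
  for (i in 1:200) {
    s <- random_dna(sample(5:40, 1), n_prob = runif(1, 0, 0.3))
    expect_identical(ambiguity_trim(s), oracle_longest_window(s))
  }
})

test_that("adapter trimming removes the first adapter occurrence or a 3' prefix", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  r <- adapter_trim(paste0("ACGT", ad, "XXXX"), ad)
  expect_true(r$keep)
  expect_identical(r$insert, "ACGT")

  expect_false(adapter_trim("ACGTACGTACGTACGT", ad)$keep)

  # adapter at position 0 gives an empty insert, later removed by length
  r0 <- adapter_trim(paste0(ad, "TTTT"), ad)
  expect_identical(r0$insert, "")
  expect_false(length_filter(r0$insert))

  # >= 10 nt adapter prefix flush with the read end is accepted
  rp <- adapter_trim(paste0("ACGTACGT", substr(ad, 1, 12)), ad)
  expect_true(rp$keep)
  expect_identical(rp$insert, "ACGTACGT")
  # a 9 nt prefix is not
  expect_false(adapter_trim(paste0("ACGTACGT", substr(ad, 1, 9)), ad)$keep)
})

test_that("length filter bounds are inclusive", {
  expect_false(length_filter(strrep("A", 14)))
  expect_true(length_filter(strrep("A", 15)))
  expect_true(length_filter(strrep("A", 55)))
  expect_false(length_filter(strrep("A", 56)))
})

test_that("UMI extraction recovers the planted UMI from simulated reads", {
  panel <- make_reference(5, seed = 9)
  sim <- simulate_reads(panel, c("isomiR-letA-5p" = 2, "isomiR-letB-5p" = 1),
                        50, seed = 13)
  for (i in seq_len(nrow(sim$reads))) {
    eu <- extract_umi(sim$reads$seq[i])
    expect_true(eu$keep)
    expect_identical(eu$umi, sim$truth$umi[i])
    expect_identical(nchar(eu$umi), 12L)
  }
  expect_false(extract_umi(strrep("A", 12), umi_len = 12)$keep)
})

test_that("perfect and equidistant inserts are weighted per the tie rule", {
  panel <- make_reference(10, seed = 21)
  # perfect match to a unique reference
  a <- assign_isomir(panel$mature_seq[5], panel)
  expect_identical(nrow(a), 1L)
  expect_identical(a$weight, 1)
  expect_identical(a$mismatches, 0L)
  expect_identical(a$name, paste0("isomiR-", panel$gene_id[5], "-",
                                  panel$arm[5]))

  # insert 1 mismatch from two family members (letA/letB differ by 1 nt):
  # mutate letA at the letA/letB difference position to a third base
  ca <- strsplit(panel$mature_seq[1], "")[[1]]
  cb <- strsplit(panel$mature_seq[2], "")[[1]]
  d <- which(ca != cb)[1]
  third <- setdiff(c("A", "C", "G", "T"), c(ca[d], cb[d]))[1]
  ca[d] <- third
  tie <- assign_isomir(paste(ca, collapse = ""), panel)
  tie <- tie[tie$offset5 == 0 & tie$offset3 == 0, ]
  expect_identical(sort(tie$gene), c("letA", "letB"))
  expect_true(all(abs(tie$weight - 1 / nrow(assign_isomir(paste(ca, collapse = ""), panel))) < 1e-12))
})

test_that("assignment equals the exhaustive alignment oracle and conserves weight", {
  set.seed(33)
  panel <- make_reference(20, seed = 20)
  for (i in 1:120) {
    base <- panel$mature_seq[sample(nrow(panel), 1)]
    ch <- strsplit(base, "")[[1]]
    # random perturbation: end trims/extensions and up to 2 substitutions
    n_mut <- sample(0:2, 1)
    if (n_mut > 0) {
      at <- sample(length(ch), n_mut)
      ch[at] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
    }
    s <- paste(ch, collapse = "")
    trim5 <- sample(0:2, 1); trim3 <- sample(0:2, 1)
    s <- substr(s, 1 + trim5, nchar(s) - trim3)
    if (runif(1) < 0.3) s <- paste0(s, random_dna(sample(1:2, 1)))
    got <- assign_isomir(s, panel)
    want <- oracle_assign(s, panel)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      key <- function(d) paste(d$gene, d$arm, d$offset5, d$offset3)
      got <- got[order(key(got)), ]
      expect_identical(key(got), key(want))
      expect_identical(got$mismatches, want$mismatches)
      expect_equal(got$weight, want$weight)
      expect_equal(sum(got$weight), 1)
    }
  }
})

test_that("UMI collapsing counts distinct molecule-isomiR pairs with fractional ties", {
  mk <- function(read, umi, name, w)
    data.frame(read_id = read, umi = umi, name = name, weight = w,
               stringsAsFactors = FALSE)
  # 5 reads, same isomiR, same UMI -> 1
  a <- do.call(rbind, lapply(1:5, function(i) mk(paste0("r", i), "U1", "iA", 1)))
  expect_identical(umi_collapse(a)$umi_count, 1)
  # 5 reads, 5 distinct UMIs -> 5
  b <- do.call(rbind, lapply(1:5, function(i)
    mk(paste0("r", i), paste0("U", i), "iA", 1)))
  expect_identical(umi_collapse(b)$umi_count, 5)
  # mixed tie fixture, hand-enumerated:
  #  U1: r1 split iA/iB 0.5 each; r2 duplicates the pair (iA) -> ignored
  #  U2: r3 full iA
  #  U3: r4 split iB/iC, r5 full iC duplicates (U3, iC) -> ignored
  #  U4: r6 full iB
  # totals: iA = 0.5 + 1 = 1.5, iB = 0.5 + 0.5 + 1 = 2.0, iC = 0.5
  m <- rbind(mk("r1", "U1", "iA", 0.5), mk("r1", "U1", "iB", 0.5),
             mk("r2", "U1", "iA", 1), mk("r3", "U2", "iA", 1),
             mk("r4", "U3", "iB", 0.5), mk("r4", "U3", "iC", 0.5),
             mk("r5", "U3", "iC", 1), mk("r6", "U4", "iB", 1))
  out <- umi_collapse(m)
  expect_equal(out$umi_count[out$isomir_name == "iA"], 1.5)
  expect_equal(out$umi_count[out$isomir_name == "iB"], 2.0)
  expect_equal(out$umi_count[out$isomir_name == "iC"], 0.5)
})

test_that("error-free simulated reads are recovered end-to-end at >= 99%", {
  panel <- make_reference(12, seed = 44)
  prof <- c("isomiR-letA-5p" = 4, "isomiR-letA-5p.t" = 3,
            "isomiR-letB-5p" = 3, "isomiR-mir1-5p" = 2,
            "isomiR-mir2-3p.a" = 2, "isomiR-mir3-5p.tt" = 1,
            "isomiR-mir4-3p.as" = 1)
  names(prof)[4:7] <- paste0("isomiR-", panel$gene_id[4:7], "-",
                             panel$arm[4:7],
                             c("", ".a", ".tt", ".as"))
  sim <- simulate_reads(panel, prof, 1500, seed = 55)
  res <- call_isomirs(sim$reads, panel)
  # per-read top assignment vs ground truth
  best <- tapply(seq_len(nrow(res$assignments)), res$assignments$read_id,
                 function(ix) {
    rows <- res$assignments[ix, ]
    rows$name[which.max(rows$weight)]
  })
  truth <- setNames(sim$truth$feature, sim$truth$id)
  hit <- mean(best == truth[names(best)])
  expect_gte(hit, 0.99)
  # count conservation: total UMI mass equals assigned molecules
  n_mol <- length(unique(res$assignments$umi))
  expect_lte(abs(sum(res$counts$umi_count) - n_mol), 1e-9)
})
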