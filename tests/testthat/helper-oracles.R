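# Independent literal oracles used by the derived-value tests. These are
# deliberately written as plain loops over the stated rules, independent of
# the vectorized implementations they check.

# Quality trimming: per-base score threshold - p, explicit running sum,
# region from first positive running sum to its maximum.
oracle_quality_trim <- function(qual, threshold = 0.05) {
  r <- 0
  run <- numeric(length(qual))
  for (i in seq_along(qual)) {
    p <- 10^(-qual[i] / 10)
    r <- r + (threshold - p)
    run[i] <- r
  }
  if (length(run) == 0 || max(run) <= 0)
    return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  start <- NA_integer_
  for (i in seq_along(run)) if (run[i] > 0) { start <- i; break }
  end <- 1L
  for (i in seq_along(run)) if (run[i] > run[end]) end <- i
  if (end < start) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  list(keep = TRUE, start = start, end = end)
}

# Longest window with <= max_n Ns: exhaustive O(L^2) scan, leftmost tie.
oracle_longest_window <- function(seq, max_n = 2L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  best <- c(start = 1L, end = 0L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (sum(ch[i:j] == "N") <= max_n && (j - i) > (best["end"] - best["start"])) {
        best <- c(start = i, end = j)
      }
    }
  }
  list(start = unname(best["start"]), end = unname(best["end"]))
}

# Exhaustive isomiR alignment: enumerate every (gene, offset5, offset3)
# with |offsets| <= 2, count mismatches character by character over the
# overlap, keep the minimal-mismatch tier, uniform weights.
oracle_assign <- function(insert, panel, max_offset = 2L, max_mismatch = 2L) {
  ins <- strsplit(toupper(insert), "")[[1]]
  li <- length(ins)
  hits <- list()
  for (g in seq_len(nrow(panel))) {
    ref <- strsplit(toupper(panel$mature_seq[g]), "")[[1]]
    lr <- length(ref)
    for (o5 in -max_offset:max_offset) {
      for (o3 in -max_offset:max_offset) {
        if (li != lr + o3 - o5) next
        mm <- 0L
        for (r in seq_len(lr)) {
          ipos <- r - o5
          if (r >= max(1, 1 + o5) && r <= min(lr, lr + o3)) {
            if (ins[ipos] != ref[r]) mm <- mm + 1L
          }
        }
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1L]] <- data.frame(
            gene = panel$gene_id[g], arm = panel$arm[g],
            offset5 = o5, offset3 = o3, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  h$weight <- 1 / nrow(h)
  h[order(h$gene, h$arm, h$offset5, h$offset3), , drop = FALSE]
}

# Benjamini-Hochberg by its step-up definition q_i = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[o[j]] * m / j)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# IPCW cumulative/dynamic AUC by explicit pair counting. The censoring
# survival function is a hand-rolled Kaplan-Meier over censoring events.
oracle_censor_km_left <- function(times, events, at) {
  ts <- sort(unique(times))
  surv <- 1
  out <- 1
  for (u in ts) {
    if (u >= at) break
    n_risk <- sum(times >= u)
    d_cens <- sum(times == u & events == 0)
    if (n_risk > 0) surv <- surv * (1 - d_cens / n_risk)
    out <- surv
  }
  out
}

oracle_auc_at <- function(risk, times, events, t) {
  num <- 0; wsum <- 0; nctrl <- 0
  n <- length(times)
  for (j in seq_len(n)) if (times[j] > t) nctrl <- nctrl + 1
  if (nctrl == 0) return(NA_real_)
  for (i in seq_len(n)) {
    if (times[i] <= t && events[i] == 1) {
      w <- 1 / oracle_censor_km_left(times, events, times[i])
      wsum <- wsum + w
      for (j in seq_len(n)) {
        if (times[j] > t) {
          if (risk[i] > risk[j]) num <- num + w
          else if (risk[i] == risk[j]) num <- num + 0.5 * w
        }
      }
    }
  }
  if (wsum == 0) return(NA_real_)
  num / (wsum * nctrl)
}

# Mantel-Cox log-rank statistic by explicit observed-minus-expected sums.
oracle_logrank <- function(times, events, group) {
  g <- as.integer(factor(group))
  o_minus_e <- 0; v <- 0
  for (u in sort(unique(times[events == 1]))) {
    at_risk <- times >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random quality strings for trimming tests.
random_qual <- function(len, lo = 0L, hi = 41L) sample(lo:hi, len, replace = TRUE)

# Random DNA sequence with optional N contamination.
random_dna <- function(len, n_prob = 0) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_prob > 0) b[runif(len) < n_prob] <- "N"
  paste(b, collapse = "")
}

# Random representable isomiR record against a panel entry.
random_record <- function(panel) {
  i <- sample(nrow(panel), 1)
  ref <- panel$mature_seq[i]
  o5 <- sample(-2:2, 1)
  o3 <- sample(-2:2, 1)
  ext <- ""
  templated <- FALSE
  if (o3 > 0) {
    repeat {
      ext <- paste(sample(c("A", "C", "G", "T"), o3, replace = TRUE),
                   collapse = "")
      templated <- runif(1) < 0.5
      if (templated || !grepl("^T+$", ext)) break
    }
  }
  n_sub <- sample(0:2, 1)
  obs_len <- nchar(ref) - max(0, o5) + o3  # rough observed length
  subs <- NULL
  if (n_sub > 0 && obs_len > 3) {
    pos <- sort(sample(seq_len(obs_len - max(0, o3)), n_sub))
    subs <- data.frame(pos = pos,
                       ref = sample(c("A", "C", "G", "T"), n_sub, TRUE),
                       obs = sample(c("A", "C", "G", "T"), n_sub, TRUE),
                       stringsAsFactors = FALSE)
  }
  isomir_record(gene = panel$gene_id[i], arm = panel$arm[i], offset5 = o5,
                offset3 = o3, substitutions = subs, ext3 = ext,
                ext3_templated = templated)
}

# Small survival fixture generator: exponential PH model on one binary
# covariate, optional random censoring.
sim_surv_binary <- function(n, log_hr, base_rate = 0.05, censor_rate = 0,
                            p_high = 0.5) {
  x <- rbinom(n, 1, p_high)
  t_ev <- rexp(n, base_rate * exp(log_hr * x))
  cc <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  list(x = x, time = pmin(t_ev, cc), event = as.integer(t_ev <= cc))
}
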