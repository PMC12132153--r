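#' Quality trimming by running-sum score
#'
#' Each base's Phred quality Q gives an error probability p = 10^(-Q/10).
#' The per-base trimming score is `threshold - p` and its running sum R is
#' scanned along the read: the kept region spans the first position where
#' R > 0 through the position where R attains its maximum. Reads whose
#' running sum never becomes positive are rejected outright.
#'
#' @param qual Integer vector of Phred qualities, or a Phred+33 quality
#'   string.
#' @param threshold Error-probability threshold in (0, 1); default 0.05.
#' @return `list(keep, start, end)`; `keep = FALSE` means the read is
#'   rejected (`start`/`end` are `NA`).
#' @export
quality_trim <- function(qual, threshold = 0.05) {
  if (is.character(qual)) qual <- utf8ToInt(qual) - 33L
  if (!length(qual)) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  if (threshold <= 0 || threshold >= 1)
    stop_invalid("threshold must be in (0, 1)")
  p <- 10^(-qual / 10)
  r <- cumsum(threshold - p)
  if (max(r) <= 0) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  start <- which(r > 0)[1]
  end <- which.max(r)
  if (end < start) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  list(keep = TRUE, start = start, end = end)
}

#' Ambiguity trimming: longest window with at most two Ns
#'
#' Returns the maximum-length contiguous region containing two or fewer
#' ambiguous nucleotides ('N'); the leftmost such window on ties.
#'
#' @param seq Nucleotide string.
#' @param max_n Maximum number of Ns tolerated in the window (default 2).
#' @return `list(start, end)` (1-based, inclusive).
#' @export
ambiguity_trim <- function(seq, max_n = 2L) {
  if (!nzchar(seq)) stop_invalid("seq must be non-empty")
  is_n <- strsplit(toupper(seq), "")[[1]] == "N"
  n <- length(is_n)
  best_len <- 0L; best_start <- 1L
  left <- 1L; n_count <- 0L
  for (right in seq_len(n)) {
    n_count <- n_count + is_n[right]
    while (n_count > max_n) {
      n_count <- n_count - is_n[left]
      left <- left + 1L
    }
    len <- right - left + 1L
    if (len > best_len) {  # strict: leftmost window wins ties
      best_len <- len
      best_start <- left
    }
  }
  list(start = best_start, end = best_start + best_len - 1L)
}

#' Adapter trimming
#'
#' Locates the 3' adapter and returns the insert 5' of it. The adapter
#' matches either as an exact full-length occurrence (first occurrence wins)
#' or as an exact prefix of at least `min_prefix` nt flush with the read's 3'
#' end (a read that ends mid-adapter). Reads without an adapter match are
#' rejected.
#'
#' @param seq Read sequence.
#' @param adapter Adapter sequence (default the QIAseq 21-mer).
#' @param min_prefix Minimum adapter prefix length accepted at the read end.
#' @return `list(keep, insert, adapter_end)` where `adapter_end` is the last
#'   read position covered by the adapter (used for UMI extraction), or
#'   `keep = FALSE` if no adapter was found.
#' @export
adapter_trim <- function(seq, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_prefix = 10L) {
  if (!nzchar(adapter)) stop_invalid("adapter must be non-empty")
  hit <- regexpr(adapter, seq, fixed = TRUE)
  if (hit > 0L) {
    return(list(keep = TRUE, insert = substr(seq, 1L, hit - 1L),
                adapter_end = hit + nchar(adapter) - 1L))
  }
  n <- nchar(seq)
  max_l <- min(nchar(adapter) - 1L, n)
  if (max_l >= min_prefix) {
    for (l in seq.int(max_l, min_prefix)) {
      if (substr(seq, n - l + 1L, n) == substr(adapter, 1L, l)) {
        return(list(keep = TRUE, insert = substr(seq, 1L, n - l),
                    adapter_end = n))
      }
    }
  }
  list(keep = FALSE, insert = NA_character_, adapter_end = NA_integer_)
}

#' Insert length filter
#'
#' @param seq Insert sequence.
#' @param lo,hi Inclusive length bounds (defaults 15 and 55).
#' @return `TRUE` if `lo <= nchar(seq) <= hi`.
#' @export
length_filter <- function(seq, lo = 15L, hi = 55L) {
  stopifnot(lo <= hi)
  n <- nchar(seq)
  n >= lo & n <= hi
}

#' Extract the UMI from a raw read
#'
#' Under the synthetic library layout (`insert + adapter + UMI + filler`)
#' the UMI is the `umi_len` bases immediately 3' of the adapter. Reads
#' whose adapter match leaves fewer than `umi_len` downstream bases are
#' rejected.
#'
#' @param seq Raw read sequence (pre adapter removal).
#' @param adapter Adapter sequence.
#' @param umi_len UMI length (default 12).
#' @return `list(keep, insert, umi)`.
#' @export
extract_umi <- function(seq, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        umi_len = 12L) {
  if (nchar(seq) <= umi_len)
    return(list(keep = FALSE, insert = NA_character_, umi = NA_character_))
  at <- adapter_trim(seq, adapter)
  if (!at$keep || at$adapter_end + umi_len > nchar(seq))
    return(list(keep = FALSE, insert = NA_character_, umi = NA_character_))
  list(keep = TRUE, insert = at$insert,
       umi = substr(seq, at$adapter_end + 1L, at$adapter_end + umi_len))
}

#' Align an insert to the reference panel and weight its isomiR assignments
#'
#' Candidate alignments place the insert against each mature reference with
#' 5' and 3' end offsets in `[-max_offset, max_offset]` and count
#' substitutions over the overlapping region (bases extending past either
#' reference end are extension bases, not mismatches). Candidates with more
#' than `max_mismatch` substitutions are discarded; among the rest only the
#' minimal-mismatch tier is kept and its k candidates each receive weight
#' 1/k (offsets carry no penalty within the window). An insert with no
#' candidate returns a zero-row table.
#'
#' @param insert Insert sequence (post trimming/filtering).
#' @param panel An `isomir_panel`.
#' @param max_offset Maximum absolute end offset (default 2).
#' @param max_mismatch Maximum substitutions (default 2).
#' @return Data frame with one row per retained candidate: `gene`, `arm`,
#'   `offset5`, `offset3`, `mismatches`, `weight`, `name`, plus a list
#'   column `record` of [isomir_record()] objects.
#' @export
assign_isomir <- function(insert, panel, max_offset = 2L, max_mismatch = 2L) {
  ins <- strsplit(toupper(insert), "")[[1]]
  li <- length(ins)
  cand <- list()
  for (g in seq_len(nrow(panel))) {
    ref <- strsplit(toupper(panel$mature_seq[g]), "")[[1]]
    lr <- length(ref)
    for (o5 in seq.int(-max_offset, max_offset)) {
      o3 <- li - lr + o5
      if (abs(o3) > max_offset) next
      # insert index of reference position r is r - o5
      r_lo <- max(1L, 1L + o5)
      r_hi <- min(lr, lr + o3)
      if (r_hi < r_lo) next
      ov_ref <- ref[r_lo:r_hi]
      ov_ins <- ins[(r_lo - o5):(r_hi - o5)]
      mm <- which(ov_ins != ov_ref)
      if (length(mm) > max_mismatch) next
      ext3 <- if (o3 > 0L) paste(ins[(li - o3 + 1L):li], collapse = "") else ""
      subs <- data.frame(pos = (r_lo:r_hi)[mm] - o5,
                         ref = ov_ref[mm], obs = ov_ins[mm],
                         stringsAsFactors = FALSE)
      # without hairpin context extensions are reported non-templated
      # (lowercase); an all-T extension must render uppercase to avoid
      # colliding with the trimming token
      rec <- isomir_record(gene = panel$gene_id[g], arm = panel$arm[g],
                           offset5 = o5, offset3 = o3, substitutions = subs,
                           ext3 = ext3,
                           ext3_templated = grepl("^T+$", ext3))
      cand[[length(cand) + 1L]] <- list(
        gene = panel$gene_id[g], arm = panel$arm[g], offset5 = o5,
        offset3 = o3, mismatches = length(mm), record = rec)
    }
  }
  if (!length(cand)) {
    return(data.frame(gene = character(), arm = character(),
                      offset5 = integer(), offset3 = integer(),
                      mismatches = integer(), weight = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  mms <- vapply(cand, `[[`, 0L, "mismatches")
  keep <- cand[mms == min(mms)]
  k <- length(keep)
  out <- data.frame(
    gene = vapply(keep, `[[`, "", "gene"),
    arm = vapply(keep, `[[`, "", "arm"),
    offset5 = vapply(keep, `[[`, 0L, "offset5"),
    offset3 = vapply(keep, `[[`, 0L, "offset3"),
    mismatches = vapply(keep, `[[`, 0L, "mismatches"),
    weight = rep(1 / k, k),
    name = vapply(keep, function(x) name_isomir(x$record), ""),
    stringsAsFactors = FALSE)
  out$record <- lapply(keep, `[[`, "record")
  out
}

#' Collapse per-read isomiR assignments to UMI counts
#'
#' One UMI is one molecule: reads sharing a UMI are PCR duplicates. Counting
#' deduplicates on distinct (UMI, isomiR) pairs — each pair contributes once,
#' with the fractional tie weight of the first read that produced it — and
#' sums the weights per isomiR. Reported UMI counts are therefore
#' real-valued, and a molecule whose reads agree contributes total mass 1
#' across isomiRs (or 0 if unassigned).
#'
#' @param assignments Data frame with columns `read_id`, `umi`, `name`,
#'   `weight` (one row per read x candidate isomiR).
#' @return Data frame `isomir_name`, `umi_count`, sorted by name.
#' @export
umi_collapse <- function(assignments) {
  if (!nrow(assignments)) {
    return(data.frame(isomir_name = character(), umi_count = numeric(),
                      stringsAsFactors = FALSE))
  }
  kept <- assignments[!duplicated(paste0(assignments$umi, "\r",
                                         assignments$name)), , drop = FALSE]
  counts <- tapply(kept$weight, kept$name, sum)
  out <- data.frame(isomir_name = names(counts),
                    umi_count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out[order(out$isomir_name), , drop = FALSE]
}

#' Call isomiRs from reads: trimming, filtering, assignment, UMI collapse
#'
#' Runs the full per-sample pipeline in order: quality trimming, ambiguity
#' trimming, adapter trimming, insert length filtering, UMI extraction,
#' reference alignment with uniform tie splitting, and UMI deduplication.
#'
#' @param reads Data frame `id`, `seq`, `qual` (see [read_fastq()]), or a
#'   FASTQ file path.
#' @param panel An `isomir_panel`.
#' @param adapter Adapter sequence.
#' @param umi_len UMI length.
#' @param quality_threshold Error threshold for [quality_trim()].
#' @param length_range Insert length bounds, default `c(15, 55)`.
#' @return List with `counts` (data frame `isomir_name`, `umi_count`),
#'   `assignments` (per-read weights) and `stats` (reads dropped per stage).
#' @export
call_isomirs <- function(reads, panel, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         umi_len = 12L, quality_threshold = 0.05,
                         length_range = c(15L, 55L)) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stats <- c(input = nrow(reads), quality = 0L, adapter = 0L, length = 0L,
             umi = 0L, unassigned = 0L)
  rows <- vector("list", nrow(reads))
  insert_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    qt <- quality_trim(reads$qual[i], quality_threshold)
    if (!qt$keep) { stats["quality"] <- stats["quality"] + 1L; next }
    seq_q <- substr(reads$seq[i], qt$start, qt$end)
    amb <- ambiguity_trim(seq_q)
    seq_a <- substr(seq_q, amb$start, amb$end)
    eu <- extract_umi(seq_a, adapter, umi_len)
    if (!eu$keep) {
      drop_stage <- if (adapter_trim(seq_a, adapter)$keep) "umi" else "adapter"
      stats[drop_stage] <- stats[drop_stage] + 1L
      next
    }
    if (!length_filter(eu$insert, length_range[1], length_range[2])) {
      stats["length"] <- stats["length"] + 1L; next
    }
    key <- eu$insert
    asn <- insert_cache[[key]]
    if (is.null(asn)) {
      asn <- assign_isomir(eu$insert, panel)
      insert_cache[[key]] <- asn
    }
    if (!nrow(asn)) { stats["unassigned"] <- stats["unassigned"] + 1L; next }
    rows[[i]] <- data.frame(read_id = reads$id[i], umi = eu$umi,
                            name = asn$name, weight = asn$weight,
                            stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(assignments)) {
    assignments <- data.frame(read_id = character(), umi = character(),
                              name = character(), weight = numeric(),
                              stringsAsFactors = FALSE)
  }
  list(counts = umi_collapse(assignments), assignments = assignments,
       stats = stats)
}
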