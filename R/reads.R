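#' Construct the observed sequence of an isomiR variant
#'
#' Applies an isomiR record to its reference mature sequence: 5' trimming
#' (`offset5 > 0`), 3' trimming (`offset3 < 0`), 3' extension
#' (`offset3 > 0`, bases taken from the record), then substitutions at their
#' 1-based positions on the observed sequence. 5' extensions (`offset5 < 0`)
#' are not constructible without hairpin context and raise an error.
#'
#' @param rec An [isomir_record()] or canonical name string.
#' @param panel An `isomir_panel` containing the record's gene/arm.
#' @return The observed variant sequence (character scalar).
#' @export
isomir_seq <- function(rec, panel) {
  if (is.character(rec)) rec <- parse_isomir_name(rec)
  validate_isomir_record(rec)
  idx <- which(panel$gene_id == rec$gene &
                 (is.na(rec$arm) | panel$arm == rec$arm))
  if (!length(idx))
    stop_invalid("gene '%s' (%s) not found in panel", rec$gene, rec$arm)
  ref <- toupper(panel$mature_seq[idx[1]])
  if (rec$offset5 < 0L)
    stop_invalid("5' extensions cannot be constructed without hairpin context")
  s <- substr(ref, 1L + rec$offset5, nchar(ref))
  if (rec$offset3 < 0L) {
    s <- substr(s, 1L, nchar(s) + rec$offset3)
  } else if (rec$offset3 > 0L) {
    s <- paste0(s, rec$ext3)
  }
  if (nrow(rec$substitutions)) {
    ch <- strsplit(s, "")[[1]]
    for (k in seq_len(nrow(rec$substitutions))) {
      p <- rec$substitutions$pos[k]
      if (p < 1L || p > length(ch))
        stop_invalid("substitution position %d outside observed sequence", p)
      ch[p] <- toupper(rec$substitutions$obs[k])
    }
    s <- paste(ch, collapse = "")
  }
  s
}

#' Simulate small-RNA sequencing reads
#'
#' Emits FASTQ-style records with the synthetic library layout
#' `insert + 3'-adapter + UMI + random filler`, padded to `read_length`.
#' Inserts are drawn from `profile` (a named non-negative abundance vector;
#' names are canonical isomiR names resolvable against `panel`) by a single
#' multinomial draw, so the number of reads carrying ground-truth label f
#' equals that draw's count for f. Qualities are constant Phred+33
#' (`Q = qual_q`). Ground-truth feature and UMI per read are returned
#' alongside the reads.
#'
#' @param panel An `isomir_panel`.
#' @param profile Named numeric vector of non-negative abundances.
#' @param n_reads Number of reads to simulate.
#' @param adapter 3' adapter sequence (default the QIAseq 21-mer).
#' @param umi_len UMI length in nt (default 12).
#' @param seed Integer seed.
#' @param read_length Total read length after padding (default 75).
#' @param qual_q Constant per-base Phred quality (default 40).
#' @return List with `reads` (data frame `id`, `seq`, `qual`) and `truth`
#'   (data frame `id`, `feature`, `umi`).
#' @export
simulate_reads <- function(panel, profile, n_reads,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           umi_len = 12L, seed = 1L, read_length = 75L,
                           qual_q = 40L) {
  if (!length(profile) || is.null(names(profile)))
    stop_invalid("profile must be a non-empty named abundance vector")
  if (any(profile < 0)) stop_invalid("abundances must be >= 0")
  if (umi_len < 1L) stop_invalid("umi_len must be >= 1")
  inserts <- vapply(names(profile), isomir_seq, "", panel = panel)
  with_seed(seed, {
    empty <- list(
      reads = data.frame(id = character(), seq = character(),
                         qual = character(), stringsAsFactors = FALSE),
      truth = data.frame(id = character(), feature = character(),
                         umi = character(), stringsAsFactors = FALSE))
    if (n_reads == 0L) return(empty)
    counts <- as.vector(stats::rmultinom(1L, n_reads, profile / sum(profile)))
    feature <- rep(names(profile), counts)
    feature <- sample(feature)  # shuffle read order
    bases <- c("A", "C", "G", "T")
    rand_str <- function(n, len) {
      vapply(seq_len(n), function(i)
        paste(sample(bases, len, replace = TRUE), collapse = ""), "")
    }
    umi <- rand_str(n_reads, umi_len)
    core <- paste0(inserts[feature], adapter, umi)
    pad <- pmax(0L, read_length - nchar(core))
    filler <- vapply(pad, function(p)
      if (p > 0L) paste(sample(bases, p, replace = TRUE), collapse = "") else "",
      "")
    seqs <- substr(paste0(core, filler), 1L, pmax(read_length, nchar(core)))
    quals <- strrep(intToUtf8(qual_q + 33L), nchar(seqs))
    ids <- sprintf("read_%06d", seq_len(n_reads))
    list(
      reads = data.frame(id = ids, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE),
      truth = data.frame(id = ids, feature = feature, umi = umi,
                         stringsAsFactors = FALSE))
  })
}

#' Write / read FASTQ (Phred+33)
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path FASTQ file path.
#' @return `read_fastq` returns a data frame `id`, `seq`, `qual`;
#'   `write_fastq` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(s), seq = as.character(s),
             qual = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE)
}

#' Ground-truth labels as JSON
#'
#' @param truth Truth data frame from [simulate_reads()].
#' @param path Output JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows")
  invisible(path)
}
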