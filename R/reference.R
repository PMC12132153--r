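#' Synthetic mature-miRNA reference panel
#'
#' Generates a miRBase-style panel of mature miRNA sequences, the alignment
#' target for isomiR calling. The panel always contains a family of
#' near-identical sequences ("letA/letB/letC", pairwise Hamming distance
#' <= 2, equal length) so that ambiguous-assignment code paths are exercised;
#' remaining genes carry independent random sequences of length 18-25 nt.
#'
#' @param n_genes Number of gene/arm entries (>= 1).
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @return A data frame of class `isomir_panel` with columns `gene_id`,
#'   `arm` and `mature_seq`.
#' @export
make_reference <- function(n_genes, seed = 1L) {
  if (!is_count_scalar(n_genes) || n_genes < 1)
    stop_invalid("n_genes must be a positive integer (got %s)",
                 deparse(n_genes))
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                    collapse = "")
    genes <- character(n_genes)
    arms <- character(n_genes)
    seqs <- character(n_genes)
    n_family <- min(3L, n_genes)
    fam_base <- strsplit(rand_seq(22L), "")[[1]]
    fam_names <- c("letA", "letB", "letC")
    for (i in seq_len(n_family)) {
      s <- fam_base
      if (i > 1L) {
        # mutate (i - 1) positions so pairwise Hamming distance stays <= 2
        at <- sample(length(s), i - 1L)
        for (p in at) s[p] <- sample(setdiff(bases, s[p]), 1L)
      }
      genes[i] <- fam_names[i]
      arms[i] <- "5p"
      seqs[i] <- paste(s, collapse = "")
    }
    if (n_genes > n_family) {
      for (i in seq.int(n_family + 1L, n_genes)) {
        genes[i] <- paste0("mir", i - n_family)
        arms[i] <- sample(c("5p", "3p"), 1L)
        seqs[i] <- rand_seq(sample(18:25, 1L))
      }
    }
    panel <- data.frame(gene_id = genes, arm = arms, mature_seq = seqs,
                        stringsAsFactors = FALSE)
    class(panel) <- c("isomir_panel", "data.frame")
    validate_panel(panel)
    panel
  })
}

validate_panel <- function(panel) {
  stopifnot(all(c("gene_id", "arm", "mature_seq") %in% names(panel)))
  if (anyDuplicated(paste(panel$gene_id, panel$arm)))
    stop_invalid("gene_id + arm pairs must be unique")
  if (any(!nzchar(panel$mature_seq)))
    stop_invalid("mature sequences must be non-empty")
  if (any(grepl("[^ACGTUN]", toupper(panel$mature_seq))))
    stop_invalid("mature sequences may only contain A, C, G, T/U, N")
  invisible(panel)
}

panel_names <- function(panel) {
  paste0("isomiR-", mapply(gene_arm_label, panel$gene_id, panel$arm,
                           USE.NAMES = FALSE))
}

#' Write / read a reference panel as FASTA
#'
#' Sequence headers are `<gene_id>-<arm>`.
#'
#' @param panel An `isomir_panel`.
#' @param path Output/input FASTA path.
#' @return `read_reference_fasta` returns an `isomir_panel`;
#'   `write_reference_fasta` returns `path` invisibly.
#' @export
write_reference_fasta <- function(panel, path) {
  validate_panel(panel)
  seqs <- Biostrings::DNAStringSet(toupper(gsub("U", "T", panel$mature_seq)))
  names(seqs) <- mapply(gene_arm_label, panel$gene_id, panel$arm,
                        USE.NAMES = FALSE)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  has_arm <- grepl("-(5p|3p)$", nm)
  arm <- ifelse(has_arm, substr(nm, nchar(nm) - 1L, nchar(nm)), NA_character_)
  gene <- ifelse(has_arm, substr(nm, 1L, nchar(nm) - 3L), nm)
  panel <- data.frame(gene_id = gene, arm = arm,
                      mature_seq = as.character(seqs),
                      stringsAsFactors = FALSE)
  class(panel) <- c("isomir_panel", "data.frame")
  validate_panel(panel)
  panel
}
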