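#' IsomiR count matrix container
#'
#' Holds a samples x features matrix of UMI counts together with the
#' missingness mask, per-sample library-preparation batch labels, the cohort
#' label, and a processing-state flag. The state advances along the fixed
#' preprocessing order `raw -> imputed -> size-normalized -> batch-adjusted
#' -> standardized`; operations check the state they require and refuse
#' out-of-order calls.
#'
#' @param values Numeric samples x features matrix (missing cells `NA` in
#'   the raw state); row names are sample ids, column names feature names.
#' @param missing Logical matrix of the same shape marking originally
#'   missing cells; defaults to `is.na(values)`.
#' @param batch Per-sample batch labels (factor or coercible).
#' @param cohort Single cohort label.
#' @param state Processing state string.
#' @param medians Optional stored per-feature raw-scale medians (set by
#'   [intersect_and_standardize()] for later dichotomization).
#' @return An object of class `isomir_matrix`.
#' @export
isomir_matrix <- function(values, missing = NULL, batch = NULL,
                          cohort = "cohort", state = "raw", medians = NULL) {
  values <- as.matrix(values)
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.matrix(missing)
  stopifnot(identical(dim(values), dim(missing)))
  dimnames(missing) <- dimnames(values)
  if (is.null(batch)) batch <- rep("b1", nrow(values))
  batch <- factor(batch)
  stopifnot(length(batch) == nrow(values))
  m <- structure(list(values = values, missing = missing, batch = batch,
                      cohort = cohort, state = state, medians = medians),
                 class = "isomir_matrix")
  validate_isomir_matrix(m)
  m
}

validate_isomir_matrix <- function(m) {
  states <- c("raw", "imputed", "size-normalized", "batch-adjusted",
              "standardized")
  if (!m$state %in% states)
    stop_invalid("unknown state '%s'", m$state)
  if (m$state %in% c("imputed", "size-normalized")) {
    if (any(m$values < 0, na.rm = TRUE))
      stop_invalid("counts must be non-negative in state '%s'", m$state)
  }
  invisible(m)
}

require_state <- function(m, allowed, op) {
  if (!m$state %in% allowed)
    stop_invalid("%s requires state %s but matrix is '%s' (pipeline order: raw -> imputed -> size-normalized -> batch-adjusted -> standardized)",
                 op, paste(sQuote(allowed), collapse = "/"), m$state)
  invisible(m)
}

#' @export
print.isomir_matrix <- function(x, ...) {
  cat(sprintf("<isomir_matrix> %d samples x %d features | cohort %s | state %s | %d batches | %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$cohort, x$state,
              nlevels(x$batch), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.isomir_matrix <- function(x) dim(x$values)

#' Write / read an isomiR count matrix as TSV with a JSON sidecar
#'
#' The TSV has samples as rows and features as columns, a header row, and
#' empty cells for missing values. Batch labels, cohort, state, and stored
#' medians go to `<path>.json`.
#'
#' @param m An `isomir_matrix`.
#' @param path TSV path.
#' @return `read_counts_tsv` returns an `isomir_matrix`.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values) %||%
                     sprintf("s%03d", seq_len(nrow(m$values))),
                   m$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  side <- list(batch = as.character(m$batch), cohort = m$cohort,
               state = m$state, medians = m$medians)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else list()
  med <- side$medians
  if (!is.null(med)) med <- unlist(med)
  isomir_matrix(vals, batch = side$batch %||% NULL,
                cohort = side$cohort %||% "cohort",
                state = side$state %||% "raw", medians = med)
}

#' Write / read a clinical survival table as TSV
#'
#' @param clinical Data frame with at least `time` and `event`.
#' @param path TSV path.
#' @export
write_survival_tsv <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
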