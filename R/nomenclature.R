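#' isomiR records and canonical nomenclature
#'
#' An isomiR record describes one observed sequence variant of a mature
#' miRNA: the reference gene and arm it derives from, its 5'/3' end offsets
#' relative to the annotated mature sequence, internal substitutions, and any
#' 3' extension bases. Records round-trip through a canonical name grammar:
#'
#' \preformatted{
#'   name  := "isomiR-" gene-arm ("." token)*
#'   token := <REF><POS><ALT>      substitution, POS 1-based on the observed
#'                                 sequence (e.g. "G9C": ref G at position 9
#'                                 read as C)
#'         | "t"+                  3' trimming, one "t" per trimmed base
#'         | [ACGT]+               3' templated extension (bases given)
#'         | [acg]+ (not all "t")  3' non-templated addition (e.g. "a")
#'         | "as" | "as<k>"        alternative 5' start; bare "as" means a
#'                                 one-base 5' trim (+1), "as2" a two-base
#'                                 trim, "as-1"/"as-2" 5' extensions
#' }
#'
#' Token order in emitted names is: substitutions (ascending position),
#' then the 5' start token, then the 3' token. A record with no deviation
#' from the reference has zero tokens. Non-templated additions consisting
#' solely of "t" are not representable (they would collide with the trimming
#' token) and raise an error.
#'
#' @param gene Gene identifier (e.g. `"let-7g"`).
#' @param arm Arm, `"5p"`, `"3p"`, or `NA` for single-arm names.
#' @param offset5 5' offset in bases, in `[-2, 2]`; positive = 5' trimming.
#' @param offset3 3' offset in bases, in `[-2, 2]`; negative = 3' trimming,
#'   positive = 3' extension of `ext3`.
#' @param substitutions Data frame with columns `pos` (1-based position on
#'   the observed sequence), `ref`, `obs`; at most two rows.
#' @param ext3 Extension bases when `offset3 > 0` (length must match).
#' @param ext3_templated Logical; `TRUE` renders the extension uppercase
#'   (templated), `FALSE` lowercase (non-templated addition).
#' @return An object of class `isomir_record`.
#' @export
isomir_record <- function(gene, arm = NA_character_, offset5 = 0L, offset3 = 0L,
                          substitutions = NULL, ext3 = "",
                          ext3_templated = FALSE) {
  if (is.null(substitutions)) {
    substitutions <- data.frame(pos = integer(), ref = character(),
                                obs = character(), stringsAsFactors = FALSE)
  }
  rec <- structure(
    list(gene = as.character(gene), arm = as.character(arm),
         offset5 = as.integer(offset5), offset3 = as.integer(offset3),
         substitutions = substitutions, ext3 = toupper(ext3),
         ext3_templated = isTRUE(ext3_templated)),
    class = "isomir_record")
  validate_isomir_record(rec)
  rec
}

validate_isomir_record <- function(rec) {
  if (abs(rec$offset5) > 2L || abs(rec$offset3) > 2L)
    stop_invalid("end offsets must lie in [-2, 2] (got 5': %d, 3': %d)",
                 rec$offset5, rec$offset3)
  if (nrow(rec$substitutions) > 2L)
    stop_invalid("at most 2 substitutions are allowed")
  if (rec$offset3 > 0L && nchar(rec$ext3) != rec$offset3)
    stop_invalid("ext3 length (%d) must equal offset3 (%d)",
                 nchar(rec$ext3), rec$offset3)
  if (rec$offset3 <= 0L && nzchar(rec$ext3))
    stop_invalid("ext3 must be empty unless offset3 > 0")
  if (rec$offset3 > 0L && !rec$ext3_templated &&
      grepl("^T+$", rec$ext3))
    stop_invalid("a non-templated addition of only 't' is not representable")
  invisible(rec)
}

gene_arm_label <- function(gene, arm) {
  if (is.na(arm) || !nzchar(arm)) gene else paste0(gene, "-", arm)
}

#' Canonical name of an isomiR record
#'
#' @param rec An [isomir_record()].
#' @return Character scalar, e.g. `"isomiR-let-7g-5p.t"`.
#' @seealso [parse_isomir_name()] for the inverse.
#' @export
name_isomir <- function(rec) {
  validate_isomir_record(rec)
  tokens <- character()
  subs <- rec$substitutions
  if (nrow(subs)) {
    subs <- subs[order(subs$pos), , drop = FALSE]
    tokens <- c(tokens, paste0(toupper(subs$ref), subs$pos, toupper(subs$obs)))
  }
  if (rec$offset5 != 0L) {
    tokens <- c(tokens, if (rec$offset5 == 1L) "as" else paste0("as", rec$offset5))
  }
  if (rec$offset3 < 0L) {
    tokens <- c(tokens, strrep("t", -rec$offset3))
  } else if (rec$offset3 > 0L) {
    tokens <- c(tokens,
                if (rec$ext3_templated) toupper(rec$ext3) else tolower(rec$ext3))
  }
  paste(c(paste0("isomiR-", gene_arm_label(rec$gene, rec$arm)), tokens),
        collapse = ".")
}

#' Parse a canonical isomiR name back into a record
#'
#' Inverse of [name_isomir()]: `parse_isomir_name(name_isomir(r))` recovers
#' `r` for every representable record. Malformed names raise an error that
#' reports the offending token and its character position within the name.
#'
#' @param name Character scalar starting with `"isomiR-"`.
#' @return An [isomir_record()].
#' @export
parse_isomir_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!startsWith(name, "isomiR-"))
    stop_invalid("parse error at position 1: name must start with 'isomiR-'")
  body <- substr(name, 8L, nchar(name))
  parts <- strsplit(body, ".", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(parts[1]))
    stop_invalid("parse error at position 8: missing gene identifier")
  ga <- parts[1]
  if (grepl("-(5p|3p)$", ga)) {
    arm <- substr(ga, nchar(ga) - 1L, nchar(ga))
    gene <- substr(ga, 1L, nchar(ga) - 3L)
  } else {
    arm <- NA_character_
    gene <- ga
  }
  offset5 <- 0L; offset3 <- 0L; ext3 <- ""; templated <- FALSE
  subs <- data.frame(pos = integer(), ref = character(), obs = character(),
                     stringsAsFactors = FALSE)
  pos_in_name <- 8L + nchar(ga)
  for (tok in parts[-1]) {
    pos_in_name <- pos_in_name + 1L  # the dot
    if (grepl("^[ACGT][0-9]+[ACGT]$", tok)) {
      m <- regmatches(tok, regexec("^([ACGT])([0-9]+)([ACGT])$", tok))[[1]]
      subs <- rbind(subs, data.frame(pos = as.integer(m[3]), ref = m[2],
                                     obs = m[4], stringsAsFactors = FALSE))
    } else if (grepl("^t+$", tok)) {
      offset3 <- -nchar(tok)
    } else if (grepl("^as(-?[0-9]+)?$", tok)) {
      k <- sub("^as", "", tok)
      offset5 <- if (nzchar(k)) as.integer(k) else 1L
    } else if (grepl("^[ACGT]+$", tok)) {
      offset3 <- nchar(tok); ext3 <- tok; templated <- TRUE
    } else if (grepl("^[acgt]+$", tok)) {
      offset3 <- nchar(tok); ext3 <- toupper(tok); templated <- FALSE
    } else {
      stop_invalid("parse error at position %d: unrecognized token '%s'",
                   pos_in_name, tok)
    }
    pos_in_name <- pos_in_name + nchar(tok)
  }
  isomir_record(gene = gene, arm = arm, offset5 = offset5, offset3 = offset3,
                substitutions = subs, ext3 = ext3, ext3_templated = templated)
}

#' @export
print.isomir_record <- function(x, ...) {
  cat("<isomir_record>", name_isomir(x), "\n")
  invisible(x)
}

#' @export
format.isomir_record <- function(x, ...) name_isomir(x)
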