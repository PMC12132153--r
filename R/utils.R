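#' @keywords internal
"_PACKAGE"

# Null-coalescing helper used throughout.
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards. With `seed = NULL` the expression runs under the
#' ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1103) %% 2147483563) + 1L
}

#' FNV-1a hash of an R object (configuration fingerprinting)
#'
#' A small dependency-free 32-bit FNV-1a hash over the deparsed object,
#' used to stamp analysis reports with the configuration that produced them.
#'
#' @param x Any R object.
#' @return Character scalar, 8 hex digits.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

is_count_scalar <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
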