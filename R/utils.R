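#' Normalize gene symbols to mouse convention
#'
#' Mouse gene symbols are conventionally written with an initial capital and
#' the remainder in lower case (e.g. `Grin1`). Input lists (BioGRID exports,
#' curated candidate lists) mix conventions, and all joins in this package are
#' by symbol, so every parser normalizes at read time.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector with first letter upper-cased, rest lower-cased;
#'   surrounding whitespace removed. `NA` and empty strings pass through.
#' @examples
#' normalize_symbol(c("GRIN1", "dcx ", "Shank3"))
#' @export
normalize_symbol <- function(x) {
  x <- trimws(as.character(x))
  out <- tolower(x)
  substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
  out[is.na(x)] <- NA_character_
  out
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations take an explicit seed and go through here so that
# results are pure functions of (inputs, seed) and callers' streams are never
# disturbed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Canonical unordered pair key "a|b" with a <= b; used to match PPI edges
# against co-expression pairs and to collapse duplicate undirected records.
pair_key <- function(a, b) {
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
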