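# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of (spec, seed) and never perturb the global stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed and a stage name
#'
#' Deterministic, stays within the 32-bit integer range, and distinct for
#' distinct stage names (FNV-1a-style string hash folded onto the seed).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1L, "spectrum")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  as.integer((as.numeric(seed) + poly_hash(stage)) %% .Machine$integer.max)
}

# Polynomial string hash kept exactly representable in doubles (31-bit).
poly_hash <- function(x) {
  h <- 17
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% 2^31
  }
  h
}

# Short stable hash of a character scalar (config fingerprinting).
str_hash <- function(x) {
  sprintf("%08x", as.integer(poly_hash(x)))
}

# Row-normalize a matrix of 3-vectors to unit norm.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("cannot normalize a zero vector")
  m / n
}
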