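# internal helpers shared across modules

# half-up rounding; base round() rounds half to even
roundHalfUp <- function(x) floor(x + 0.5)

#' Derive a child seed from a root seed
#'
#' Deterministic splitting scheme used everywhere a single root seed has to
#' drive several independent random draws (per-layer expression tables,
#' per-edge rewiring, per-stage experiment randomness): child i of root s is
#' `(s * 48271 + i * 2654435769) mod (2^31 - 1)`, a multiplicative-congruence
#' mix that keeps all derived seeds inside the 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param index non-negative integer child index.
#' @return integer child seed in \[1, 2^31 - 2\].
#' @export
childSeed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + (as.numeric(index) %% m) * 2654435769
  as.integer(s %% m + 1)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

assertScalarCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
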