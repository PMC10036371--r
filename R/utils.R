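# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Sets the Mersenne-Twister stream to `seed`, evaluates `expr`, and restores
#' the caller's RNG state so library code never perturbs user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a root seed with integer indices (subject, block, ...) into a new
#' seed below 2^31, so that every simulated unit gets an independent,
#' deterministic stream.
#'
#' @param seed root integer seed.
#' @param ... integer indices identifying the sub-stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) {
    # LCG-style mixing; constants are primes, kept in double precision range
    x <- (x * 48271 + as.double(i) * 104729 + 7919) %% 2147483647
  }
  as.integer(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x > 0
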