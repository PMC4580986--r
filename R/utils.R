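# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed` and then
#' restores the caller's RNG state, so library code never perturbs a user's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

# Named per-stage substreams derived from one global seed.  The modulus keeps
# every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) %% 1e6) * 1009 + 7919 * as.numeric(stream) %% 2147483629
}

is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (x > 0 || (!positive && x == 0))
}

# p-values live in (0, 1]; numeric underflow in extreme tails is clamped to
# the smallest representable positive double rather than reported as 0.
clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)
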