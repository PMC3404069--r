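# Internal helpers shared across modules.

#' Derive a stream-specific RNG seed from a base seed and an index
#'
#' Per-gene (and per-stage) seeds are derived deterministically so that genes
#' can be processed in any order, or in parallel, with identical results.
#' The derived seed stays inside the 32-bit signed integer range R requires.
#'
#' @param seed base integer seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647            # 2^31 - 1, prime
  s <- (as.double(seed) %% m) + 1
  # two rounds of a Lehmer-style mix keep distinct (seed, index) pairs apart
  s <- (s * 48271 + as.double(index) * 69621) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(s %% (m - 1) + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call. = FALSE and sprintf formatting
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort_fmt("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) abort_fmt("'%s' must be a probability in %s%g, %g%s", name,
                     if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  as.numeric(x)
}
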