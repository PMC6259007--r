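#' Derive a child random seed from a master seed
#'
#' Streams of randomness for the groups of a scenario (or the stages of a
#' bootstrap) are separated by deriving child seeds from one master seed with
#' a multiplicative mixing step, so that adding a new consumer never shifts
#' the draws of an existing one. Seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param k stream index (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(seed) %% m)
  # Lehmer step per stream index, offset so k = 0 still mixes
  x <- (x * 48271 + (k + 1) * 2246822519) %% m
  x <- (x * 48271) %% m
  as.integer(max(1, x %% (m - 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
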