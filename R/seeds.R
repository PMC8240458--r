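#' Derive a reproducible sub-stream seed
#'
#' Every stochastic stage of a simulation (medium sampling, probe patterns,
#' measurement noise, genetic search) should consume its own seed so that each
#' stage is independently reproducible. `derive_seed()` maps a base seed plus a
#' stream label (and an optional replicate index) to a deterministic integer
#' below 2^31, using a small multiplicative hash.
#'
#' @param seed Integer base seed.
#' @param stream Character label of the sub-stream, e.g. `"tm"`, `"noise"`,
#'   `"patterns"`, `"ga"`.
#' @param index Non-negative integer replicate index (default 0).
#' @return A single integer in `[1, 2^31 - 2]`, deterministic in its inputs.
#' @examples
#' derive_seed(1, "tm")
#' derive_seed(1, "tm", index = 3)
#' @export
derive_seed <- function(seed, stream = "default", index = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stopifnot(is.character(stream), length(stream) == 1)
  stopifnot(is.numeric(index), length(index) == 1, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  codes <- c(utf8ToInt(stream), 257, index + 1)
  for (ch in codes) {
    # 16807 = 7^5, the Lehmer/Park-Miller multiplier; all arithmetic stays
    # below 2^53 so doubles carry it exactly
    h <- (h * 16807 + ch) %% m
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards, so that seeded helpers do not disturb an enclosing
#' stochastic computation (e.g. noise injection inside a genetic-algorithm
#' run).
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_stream_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
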