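# Deterministic seed derivation for reproducible simulation streams.

#' Derive a child seed from a base seed and one or more indices
#'
#' Splittable seed derivation used throughout the package: the scenario seed
#' is derived from a base seed and the scenario index, and replicate `r`
#' within a scenario uses the child seed `derive_seed(scenario_seed, r)`.
#' The map is a multiplicative congruential mix modulo the Mersenne prime
#' 2^31 - 1, so derived seeds always fit a 32-bit integer and distinct
#' (base, index) pairs give well-separated streams.
#'
#' @param base Integer base seed.
#' @param ... One or more non-negative integer indices.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L, all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(base) %% m
  for (k in as.double(idx)) {
    # two rounds of multiply-add mixing; all products stay below 2^53
    s <- (s * 48271 + (k %% m) + 1) %% m
    s <- (s * 69621 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
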