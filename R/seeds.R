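# Deterministic sub-seed derivation. One root seed is split into independent
# sub-streams (network / genotypes / noise / per-gene samplers) so each part
# of a run is reproducible on its own and per-gene inference is independent
# of row execution order. A multiplicative-congruential mix over the prime
# 2^31 - 1 keeps every derived seed a valid 32-bit R integer.

#' Derive a reproducible sub-seed from a root seed
#'
#' @param seed Root integer seed.
#' @param stream Integer stream index (>= 0); distinct streams give
#'   distinct, deterministic sub-seeds.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(stream), length(stream) == 1, stream >= 0)
  p <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% p)
  out <- (s * 48271 + as.double(stream) * 16807 + 1) %% p
  as.integer(out %% (p - 1) + 1)
}
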