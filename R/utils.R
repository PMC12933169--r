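#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus any number of integer stream
#' identifiers (cluster index, subset size, ...) to a child seed in
#' `[1, 2^31 - 2]`, via a Lehmer-style multiplicative mix. Lets any single
#' stage of a larger run be reproduced in isolation.
#'
#' @param seed Master seed (integer).
#' @param ... Integer stream identifiers.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483647  # 2^31 - 1, prime
  x <- as.numeric(seed) %% mod
  for (id in c(...)) {
    x <- (x * 48271 + as.numeric(id) + 1) %% mod
  }
  as.integer(x %% (mod - 1)) + 1L
}
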