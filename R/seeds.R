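#' Derive a reproducible sub-seed
#'
#' Mixes a global seed with any number of integer indices (experiment,
#' landscape index, cohort index, ...) into a seed in `[1, 2^31 - 2]`.
#' Every stochastic path in an experiment derives its stream this way, so
#' cohorts are order-independent: running replicate 57 alone gives the same
#' result as running it within the full design.
#'
#' @param seed Global integer seed.
#' @param ... Non-negative integer indices identifying the sub-stream.
#' @return An integer seed.
#' @export
seed_stream <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime; Lehmer-style mixing)
  h <- (as.numeric(seed) %% m + m) %% m
  for (k in c(...)) {
    h <- (h * 48271) %% m
    h <- (h + (as.numeric(k) + 1) * 69621) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}
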