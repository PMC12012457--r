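#' Derive a module-specific seed from a global seed
#'
#' One global seed fans out to named per-stage random streams so each
#' pipeline stage is independently reproducible. The derived seed is a
#' deterministic 31-bit hash of the global seed and the stream name.
#'
#' @param seed Non-negative integer global seed.
#' @param stream Character name of the stream (e.g. \code{"cohort"},
#'   \code{"ties"}, \code{"eiv"}).
#' @return An integer seed in \code{[0, 2^31 - 1)}.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, is.character(stream))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporarily-seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
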