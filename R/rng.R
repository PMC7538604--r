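#' Derive a named random substream seed
#'
#' All stochastic steps in the package draw from substreams derived
#' deterministically from one global seed, so that a whole run is reproducible
#' from a single integer while independent steps (scene generation, occlusion
#' draws, neurogenesis, ...) do not share a stream.
#'
#' @param seed Integer global seed.
#' @param name Character label of the substream.
#' @param index Optional nonnegative integer distinguishing repeated uses of
#'   the same substream (e.g. draw number).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(42, "occlusion", 3)
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- (as.numeric(seed) %% m)
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

# run expr under a local RNG state seeded from a substream; restores the
# caller's .Random.seed so library code never perturbs user randomness
with_substream <- function(seed, name, index = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name, index))
  expr
}
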