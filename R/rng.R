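# Independent seeded RNG streams.
#
# Training uses three sources of randomness (data order, feature noise,
# weight initialization). Keeping each in its own stream means an ablation
# that changes one source leaves the others bit-identical. A stream stores a
# private copy of .Random.seed and swaps it in only while drawing.

#' Create an independent seeded RNG stream
#'
#' @param seed Integer seed.
#' @return An `rng_stream` object usable with [make_batches()] and
#'   [perturb_features()].
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Deterministic per-scene seed below 2^31, mixing a user seed with an index.
mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 1) %%
               2147483647)
}
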