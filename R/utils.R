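#' Derive a child seed from a master seed
#'
#' Folds one or more integer indices into a master seed with a Lehmer-style
#' multiplicative congruential step, `s <- (s * 48271 + idx) mod (2^31 - 1)`.
#' The same (seed, indices) pair always yields the same child seed, children
#' of distinct indices are effectively independent, and every child stays
#' below 2^31 so it is a valid R integer seed. All stochastic stages of the
#' package (subject sampling, cycle generation, balanced resampling,
#' train/test splitting, network initialization) draw their seeds through
#' this function, which makes any single repetition of a repeated experiment
#' replayable in isolation.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the stage/repetition.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' fold_seed(42, 1, 3)
fold_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed) %% m
  for (idx in as.double(c(...))) {
    # 48271 * (m - 1) + idx < 2^53, so double arithmetic is exact here
    s <- (s * 48271 + idx) %% m
  }
  if (s < 1) s <- s + 1
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. With seed = NULL the ambient RNG is used directly.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gs <- function(...) stop(..., call. = FALSE)
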