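#' Deterministic sub-stream seeding
#'
#' The simulator draws random numbers in several independent places (noise
#' per shot, dynamic plane selection per frame). So that shots and frames
#' can be computed in any order — or concurrently — and still reproduce the
#' sequential run bit-exactly, every draw is made under a sub-seed derived
#' deterministically from the master seed and a counter (shot or frame
#' index), never from the global RNG stream position.
#'
#' `mix_seed()` combines master seed and counters into a single positive
#' 31-bit integer by an LCG-style mix (all intermediates stay below 2^53 so
#' the arithmetic is exact in doubles on every platform).
#'
#' @param seed master seed (integer)
#' @param ... integer counters (e.g. shot index, frame index)
#' @return a positive integer suitable for `set.seed()`
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.double(seed) %% m
  for (k in c(...)) {
    h <- (h * 48271 + (as.double(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
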