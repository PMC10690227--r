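#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-family / per-gene / per-stage
#' substream seeds with a counter-based mix, so that any subset of a
#' simulation can be regenerated without running the whole study. The result
#' always fits in a 32-bit signed integer.
#'
#' @param seed integer global seed.
#' @param ... one or more non-negative integer counters (e.g. family index,
#'   gene index, stage code).
#' @return a single integer seed.
#' @export
substream_seed <- function(seed, ...) {
  ks <- c(...)
  stopifnot(length(ks) >= 1L, all(is.finite(ks)))
  h <- as.double(seed) %% 2147483647
  for (k in ks) {
    # multiplicative mixing mod the Mersenne prime 2^31 - 1
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
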