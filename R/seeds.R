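#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single integer master seed. Each
#' stochastic operation derives its own substream seed by hashing the master
#' seed together with a string tag (and, where relevant, a subject or
#' replicate counter), so that identical master seeds give identical results
#' across runs while distinct operations never share a random stream.
#'
#' @param seed Integer master seed.
#' @param ... Further tags (strings or integers) identifying the substream,
#'   e.g. an operation name and a subject index.
#' @return A single integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "dynamics", "rate", 3)
#' @export
substream_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 31 + ch) %% 2147483647
    h <- (h * 31 + 7) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a derived substream seed, restoring the caller's RNG state.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, ...))
  expr
}
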