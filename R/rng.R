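#' Derive a reproducible substream seed from a root seed and a stream name
#'
#' All randomness in the package is routed through named substreams derived
#' from one root seed, so individual modalities (moment noise, speckle, sEMG
#' noise, weight initialization, shuffling) can be regenerated independently
#' while the whole pipeline stays bit-reproducible.
#'
#' @param root_seed integer root seed.
#' @param stream character stream name, e.g. `"speckle"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(root_seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  # simple FNV-style rolling hash over the stream name, folded with the root
  h <- 2166136261
  for (ch in utf8ToInt(stream)) {
    h <- (h * 16777619 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(root_seed) %% 2147483647) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so library code does not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed for the scoped evaluation.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
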