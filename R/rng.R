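#' Derive a deterministic sub-seed from a base seed and a label
#'
#' Every stage and every per-index substream in the package draws its seed
#' through this function, so a single experiment seed fully determines all
#' randomness while stages stay independent of each other's draw counts.
#'
#' Uses a small multiplicative string hash folded into the base seed; the
#' result is a non-negative integer strictly below 2^31 - 1, suitable for
#' `set.seed()`.
#'
#' @param seed integer base seed.
#' @param label character scalar naming the substream (e.g. `"codec_image"`),
#'   or an integer index.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "diffusion") != derive_seed(1L, "codec_image")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  label <- as.character(label)
  m <- 2147483647 # 2^31 - 1, Mersenne prime keeps the fold well mixed
  h <- (as.double(seed) %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  # avoid the degenerate 0 seed
  as.integer(h) + 1L
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so library internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
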