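# Seed handling.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded internals (bootstraps, simulations) do not perturb the session's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a root seed
#'
#' Deterministically maps (root seed, stage label) to a 31-bit integer so a
#' single root seed reproduces a whole multi-stage run while stages use
#' distinct streams.
#'
#' @param seed Integer root seed.
#' @param stage Character stage label.
#' @return Integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, length(stage) == 1L)
  h <- utils::head(utf8ToInt(paste0(stage, ":", format(seed))), 50L)
  acc <- 0
  for (v in h) acc <- (acc * 131 + v) %% 2147483647
  as.integer(acc)
}
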