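#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded estimators do not disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  set.seed(seed)
  expr
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' A single pipeline seed fans out to independent stage seeds by hashing the
#' stage name, so stages can be rerun in isolation and still reproduce.
#'
#' @param seed Master integer seed.
#' @param name Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
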