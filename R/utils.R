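# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All stochastic operations in the package funnel their `seed` argument
#' through this helper so that identical seeds give bit-identical results and
#' the global RNG stream of the calling session is never disturbed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Mix a retry/stream counter into a base seed, staying inside 32-bit range.
mix_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
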