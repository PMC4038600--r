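# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed (when non-NULL), evaluates, and restores the caller's RNG
#' state so that seeded calls never perturb the global random stream.
#'
#' @param seed integer seed or `NULL` (use the current stream).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a reproducible child seed from a master seed and a tag
#'
#' Deterministic integer hash so that every stochastic stage of a run gets its
#' own stream, independent of execution order (e.g. pairwise tests).
#'
#' @param master integer master seed.
#' @param tag character tag naming the stage (e.g. `"permanova:CladeA|CladeB"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, tag) {
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
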