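# internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
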