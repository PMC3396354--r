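# Internal helpers shared across modules.

#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_config("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

# Run an expression with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
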