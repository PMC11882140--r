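## internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves `.Random.seed`, seeds the generator, evaluates `expr`, and restores
#' the previous state so that seeded internals (e.g. Monte-Carlo Dunnett
#' critical values) do not perturb the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper)
    stop_invalid("`%s` = %g is outside the allowed range", name, x)
  invisible(x)
}

## population (n-denominator) standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
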