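# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
divgrad_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "divgrad_error"), call = call))
}

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state so
#' that seeded internals never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Round halves away from zero (commercial rounding); diversity estimators
# need integer frequencies and R's round() rounds halves to even.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lower = -Inf, upper = Inf) pmin(pmax(x, lower), upper)

# Format numerics so that write/read round-trips are exact for doubles.
format_num <- function(x) {
  out <- vapply(x, function(z) {
    if (is.na(z)) return("")
    if (is.finite(z) && z == round_half_up(z) && abs(z) < 1e15) {
      # integral values print without exponent for readability
      sprintf("%.0f", z)
    } else {
      sprintf("%.17g", z)
    }
  }, character(1))
  out
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}
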