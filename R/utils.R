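# internal helpers

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (if (strict_lower) x <= lower else x < lower) {
    stopf("`%s` must be %s %s", name, if (strict_lower) ">" else ">=", lower)
  }
  if (if (strict_upper) x >= upper else x > upper) {
    stopf("`%s` must be %s %s", name, if (strict_upper) "<" else "<=", upper)
  }
  invisible(x)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# number of values of x falling outside [0, 1] before clamping
n_clamped <- function(x) sum(x < 0 | x > 1)
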