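# internal argument checks; all errors name the offending field

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field),
          class = "camiks_validation_error")
  }
  ok_lower <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    abort(sprintf("`%s` = %g is outside the allowed range.", field, x),
          class = "camiks_validation_error")
  }
  invisible(x)
}

check_positive <- function(x, field) {
  check_number(x, field, lower = 0, allow_zero_lower = FALSE)
}

check_non_negative <- function(x, field) {
  check_number(x, field, lower = 0)
}

check_increasing <- function(x, field) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(diff(x) <= 0)) {
    abort(sprintf("`%s` must be a strictly increasing numeric vector.", field),
          class = "camiks_validation_error")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", field, min),
          class = "camiks_validation_error")
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  check_count(seed, "seed", min = 0L)
}

# run an expression under a locally fixed RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# gas constant, kcal mol^-1 K^-1
R_KCAL <- 1.9872e-3
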