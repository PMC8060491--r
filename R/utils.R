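# Shared internal helpers: classed conditions, seeded RNG scope, validation.

vf_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "vascflow_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

vf_check <- function(cond, class, msg) {
  if (!isTRUE(cond)) vf_error(class, msg)
  invisible(TRUE)
}

# Evaluate expr with the RNG seeded to `seed`, restoring global RNG state on
# exit, so no call leaks randomness into or out of the session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

is_num1 <- function(x, min = -Inf, strict = FALSE) {
  is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
}

check_finite_vector <- function(x, name, min_len = 1) {
  vf_check(is.numeric(x) && length(x) >= min_len, "vascflow_parameter_error",
           sprintf("`%s` must be numeric with at least %d values", name, min_len))
  vf_check(all(is.finite(x)), "vascflow_parameter_error",
           sprintf("`%s` contains non-finite values", name))
  invisible(TRUE)
}
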