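# Internal helpers shared across modules.

# Signal a classed error so callers (and the CLI) can react by condition class.
gt_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "gt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  seed = NULL leaves the current stream untouched.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal rule on (possibly non-uniform) abscissae.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is_scalar_number(x))
    gt_stop(sprintf("`%s` must be a single finite number", name), "gt_argument_error")
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    gt_stop(sprintf("`%s` must be %s %g (got %g)", name,
                    if (strict) ">" else ">=", lower, x),
            "gt_argument_error")
  invisible(x)
}
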