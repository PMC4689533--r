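# Internal helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL runs `expr` on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Sanity-check a numeric data vector.
check_series <- function(x, min_n = 1L, what = "sample") {
  if (!is.numeric(x)) stop("'", what, "' must be numeric")
  if (length(x) < min_n)
    stop("'", what, "' must contain at least ", min_n, " values")
  if (anyNA(x) || any(!is.finite(x)))
    stop("'", what, "' contains missing or non-finite values")
  invisible(as.numeric(x))
}

# Trapezoidal cumulative integral of y over x (uniform or not).
cum_trapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
}
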