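# Independent brute-force oracles used across the test files. These stay
# deliberately naive (double loops, explicit interpolation formulas) so they
# cannot share a bug with the implementation under test.

# ECF by explicit double summation
brute_ecf <- function(x, k) {
  vapply(k, function(kk) {
    acc <- 0 + 0i
    for (xi in x) acc <- acc + exp(1i * kk * xi)
    acc / length(x)
  }, complex(1))
}

# quantile by linear interpolation between order statistics:
# h = (n - 1) p + 1, value = x_(floor h) + (h - floor h)(x_(floor h + 1) - x_(floor h))
brute_quartile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# brute-force box-plot pieces under the 1.5 IQR rule
brute_box <- function(x) {
  q1 <- brute_quartile(x, 0.25)
  q3 <- brute_quartile(x, 0.75)
  lo <- q1 - 1.5 * (q3 - q1)
  hi <- q3 + 1.5 * (q3 - q1)
  out <- x[x < lo | x > hi]
  inn <- x[x >= lo & x <= hi]
  list(Q1 = q1, Q3 = q3, outliers = out,
       whisker_low = min(inn), whisker_high = max(inn))
}

# two-sample KS distance by enumeration over every jump point
brute_ks2 <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# log of the tempered stable CF (real-valued), for numerical cumulants
tempered_lcf <- function(k, alpha, lambda) {
  2 * Re(complex(real = lambda, imaginary = k)^alpha) - 2 * lambda^alpha
}

# numerical cumulants of the tempered stable law from central differences
# of log phi at 0 (variance = -2nd derivative, 4th cumulant = 4th derivative)
tempered_num_cumulants <- function(alpha, lambda, h = 1e-2) {
  f <- function(k) tempered_lcf(k, alpha, lambda)
  d2 <- (f(h) - 2 * f(0) + f(-h)) / h^2
  d4 <- (f(2 * h) - 4 * f(h) + 6 * f(0) - 4 * f(-h) + f(-2 * h)) / h^4
  list(var = -d2, k4 = d4)
}

# construct a bare alpha_curve object from given estimates (for rule tests)
fake_curve <- function(alphas) {
  structure(list(K_levels = seq_along(alphas), alpha_hats = alphas,
                 n = 2000L, clipped = alphas >= 2),
            class = "alpha_curve")
}
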