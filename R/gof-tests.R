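# EDF-based comparison tests: one- and two-sample Kolmogorov-Smirnov,
# Jarque-Bera, and a parametric-bootstrap Anderson-Darling test for the
# stable law. Results are returned as "htest"-style objects so the standard
# print method applies.

#' Empirical distribution function
#'
#' Right-continuous step function \eqn{F_n} with jumps of \eqn{1/n} at the
#' sorted sample points (ties stack). Thin wrapper around
#' \code{\link[stats]{ecdf}}.
#'
#' @param x non-empty numeric sample.
#' @return A function of class \code{"ecdf"}.
#' @examples
#' edf(c(1, 1, 2))(1)  # 2/3
#' @export
edf <- function(x) {
  x <- check_series(x, what = "x")
  stats::ecdf(x)
}

# Kolmogorov asymptotic survival function P(sqrt(n) D >= t)
kolmogorov_sf <- function(t) {
  if (t < 0.05) return(1)
  j <- seq_len(101L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(max(p, 0), 1)
}

new_tail_test <- function(statistic, p_value, method, data_name, details) {
  structure(list(statistic = statistic, p.value = p_value, method = method,
                 data.name = data_name, details = details),
            class = c("tail_test", "htest"))
}

#' One-sample Kolmogorov-Smirnov test
#'
#' Supremum EDF statistic \eqn{D = \sup_x |F_n(x) - F(x)|}, computed exactly
#' at the sample points (both one-sided gaps), with the p-value
#' \eqn{P(D \ge t)} from the asymptotic Kolmogorov distribution.
#'
#' @param x numeric sample.
#' @param cdf a vectorized continuous distribution function returning values
#'   in [0, 1].
#' @return An \code{"htest"}-style object with \code{statistic} (D) and
#'   \code{p.value}.
#' @examples
#' ks_one_sample(rnorm(100), pnorm)
#' @export
ks_one_sample <- function(x, cdf) {
  x <- check_series(x, what = "x")
  if (!is.function(cdf)) stop("'cdf' must be a function")
  n <- length(x)
  Fv <- cdf(sort(x))
  if (anyNA(Fv) || any(Fv < 0 | Fv > 1))
    stop("'cdf' returned values outside [0, 1]")
  i <- seq_len(n)
  D <- max(i / n - Fv, Fv - (i - 1) / n)
  new_tail_test(c(D = D), kolmogorov_sf(sqrt(n) * D),
                "One-sample Kolmogorov-Smirnov test (asymptotic p-value)",
                deparse(substitute(x)), list(n = n))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D_2 = \sup_x |F_{1,n}(x) - F_{2,n}(x)|}, evaluated over all jump
#' points of either EDF, with the asymptotic Kolmogorov p-value at effective
#' size \eqn{n_1 n_2 / (n_1 + n_2)}.
#'
#' @param x,y non-empty numeric samples.
#' @return An \code{"htest"}-style object with \code{statistic} (D2) and
#'   \code{p.value}.
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100))
#' @export
ks_two_sample <- function(x, y) {
  x <- check_series(x, what = "x")
  y <- check_series(y, what = "y")
  z <- sort(unique(c(x, y)))
  D2 <- max(abs(edf(x)(z) - edf(y)(z)))
  ne <- length(x) * length(y) / (length(x) + length(y))
  new_tail_test(c(D2 = D2), kolmogorov_sf(sqrt(ne) * D2),
                "Two-sample Kolmogorov-Smirnov test (asymptotic p-value)",
                paste(deparse(substitute(x)), "vs", deparse(substitute(y))),
                list(n1 = length(x), n2 = length(y)))
}

#' Standardize a series to zero mean and unit standard deviation
#'
#' @param x numeric series with positive variance.
#' @return \code{(x - mean(x)) / sd(x)}.
#' @examples
#' normalize_series(c(0, 2))
#' @export
normalize_series <- function(x) {
  x <- check_series(x, min_n = 2L, what = "x")
  s <- stats::sd(x)
  if (s == 0) stop("cannot normalize a zero-variance series")
  (x - mean(x)) / s
}

#' Jarque-Bera test for Gaussianity
#'
#' \eqn{JB = \frac{n}{6}\left(S^2 + \frac{(\mathrm{Kurt}-3)^2}{4}\right)}
#' with moment-based sample skewness \eqn{S} and kurtosis Kurt. The p-value
#' is chi-square(2) by default; \code{n_mc > 0} switches to a Monte-Carlo
#' null (simulated Gaussian samples of the same size), useful for small
#' samples.
#'
#' @param x numeric sample of at least 20 values with positive variance.
#' @param n_mc number of Monte-Carlo null replicates (0 = asymptotic
#'   chi-square p-value).
#' @param seed optional integer for the Monte-Carlo mode.
#' @return An \code{"htest"}-style object.
#' @examples
#' jarque_bera(rnorm(200))
#' @export
jarque_bera <- function(x, n_mc = 0L, seed = NULL) {
  x <- check_series(x, min_n = 20L, what = "x")
  if (stats::var(x) == 0) stop("zero-variance sample")
  jb <- jb_stat(x)
  n <- length(x)
  p <- if (n_mc > 0) {
    null_jb <- with_seed(seed, vapply(seq_len(n_mc), function(i)
      jb_stat(stats::rnorm(n)), numeric(1)))
    mean(null_jb >= jb)
  } else {
    stats::pchisq(jb, df = 2, lower.tail = FALSE)
  }
  new_tail_test(c(JB = jb), p,
                if (n_mc > 0) "Jarque-Bera test (Monte-Carlo p-value)"
                else "Jarque-Bera test (chi-square p-value)",
                deparse(substitute(x)), list(n = n, n_mc = n_mc))
}

jb_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / m2^1.5
  Kurt <- mean((x - m)^4) / m2^2
  n / 6 * (S^2 + (Kurt - 3)^2 / 4)
}

#' Anderson-Darling test for the stable law
#'
#' Fits stable parameters to the sample with \code{\link{estimate_stable}},
#' computes the Anderson-Darling quadratic EDF statistic against the fitted
#' stable CDF (obtained by numerical inversion of the characteristic
#' function, cached for the fit), and obtains the p-value by parametric
#' bootstrap: \code{n_boot} samples are simulated from the fitted law,
#' re-fitted, and the statistic recomputed; the p-value is the proportion of
#' bootstrap statistics at or above the observed one (so it lies on the grid
#' \code{0, 1/n_boot, ..., 1}).
#'
#' @param x numeric sample of at least 100 values.
#' @param n_boot number of parametric bootstrap replicates (default 1000;
#'   200 already gives a usable p-value resolution of 0.005).
#' @param seed optional integer making the bootstrap deterministic.
#' @return An \code{"htest"}-style object whose \code{details} carry the
#'   fitted \code{\link{stable_params}} and the seed.
#' @examples
#' \donttest{
#' ad_stable(stable_rvs(500, stable_params(1.9, 1), seed = 1),
#'           n_boot = 100, seed = 2)
#' }
#' @export
ad_stable <- function(x, n_boot = 1000L, seed = NULL) {
  x <- check_series(x, min_n = 100L, what = "x")
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 100)
    stop("'n_boot' must be an integer of at least 100")
  fit <- estimate_stable(x)
  A2 <- ad_stat(x, stable_cdf_fun(fit$params))
  n <- length(x)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    xb <- stable_rvs(n, fit$params)
    fb <- estimate_stable(xb)
    ad_stat(xb, stable_cdf_fun(fb$params))
  }, numeric(1)))
  new_tail_test(c(A2 = A2), mean(boot >= A2),
                "Anderson-Darling test for the stable law (parametric bootstrap)",
                deparse(substitute(x)),
                list(n = n, n_boot = as.integer(n_boot),
                     fitted = fit$params, seed = seed))
}

ad_stat <- function(x, F) {
  n <- length(x)
  u <- F(sort(x))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}
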