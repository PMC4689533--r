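# Domain-of-attraction discrimination: block aggregation, the alpha-vs-K
# curve, bootstrap box plots, and the light/heavy verdict.
#
# Block sums are never renormalized: the regression estimator of alpha is
# scale- and location-invariant, so the CLT-style norming constants would
# cancel anyway.

#' Block aggregation of a series
#'
#' Divides the series into non-overlapping consecutive blocks of length
#' \code{K}, starting at the first observation, and sums within each block.
#' The result has length \code{floor(N / K)}; a trailing remainder of
#' \code{N %% K} values is discarded. \code{K = 1} returns the series
#' unchanged.
#'
#' @param x numeric series of length \code{N >= K}.
#' @param K block length, a positive integer.
#' @return Numeric vector of \code{floor(N / K)} block sums.
#' @examples
#' block_aggregate(c(1, 2, 3, 4, 5), 2)  # c(3, 7)
#' @export
block_aggregate <- function(x, K) {
  x <- check_series(x, what = "x")
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != floor(K))
    stop("'K' must be a positive integer")
  n <- length(x)
  if (K > n) stop("block length K = ", K, " exceeds the series length ", n)
  if (K == 1) return(x)
  m <- n %/% K
  .colSums(matrix(x[seq_len(m * K)], nrow = K), K, m)
}

#' Stability index as a function of aggregation level
#'
#' For each block length \code{K = 1, ..., K_max}, aggregates the series with
#' \code{\link{block_aggregate}} and estimates the index of stability of the
#' aggregated data with \code{\link{estimate_stable}}. For data in the
#' Gaussian domain of attraction the estimates drift toward 2 as \code{K}
#' grows; for exact stable data the curve is flat at the true index.
#'
#' @param x numeric series.
#' @param K_max number of aggregation levels (default 10); the aggregated
#'   series at the deepest level, of length \code{floor(N / K_max)}, must be
#'   at least as long as the estimator's documented minimum.
#' @param ... passed to \code{\link{estimate_stable}}.
#' @return An object of class \code{"alpha_curve"}: list with
#'   \code{K_levels}, \code{alpha_hats} (each in (0, 2]), \code{n}, and a
#'   per-level clipping flag \code{clipped}.
#' @examples
#' ac <- alpha_curve(stable_rvs(2000, stable_params(1.9, 1), seed = 1))
#' @export
alpha_curve <- function(x, K_max = 10L, ...) {
  x <- check_series(x, what = "x")
  if (!is.numeric(K_max) || length(K_max) != 1L || K_max < 1 ||
      K_max != floor(K_max))
    stop("'K_max' must be a positive integer")
  n <- length(x)
  if (n %/% K_max < 50L)
    stop("series too short: floor(N / K_max) = ", n %/% K_max,
         " is below the estimator's minimum length of 50")
  ah <- numeric(K_max)
  cl <- logical(K_max)
  for (K in seq_len(K_max)) {
    fit <- tryCatch(estimate_stable(block_aggregate(x, K), ...),
                    error = function(e)
                      stop("estimation failed at aggregation level K = ", K,
                           ": ", conditionMessage(e), call. = FALSE))
    ah[K] <- fit$params$alpha
    cl[K] <- fit$diagnostics$clipped
  }
  structure(list(K_levels = seq_len(K_max), alpha_hats = ah, n = n,
                 clipped = cl),
            class = "alpha_curve")
}

#' @export
print.alpha_curve <- function(x, ...) {
  cat("estimated stability index by aggregation level (n =", x$n, "):\n")
  print(stats::setNames(round(x$alpha_hats, 4), paste0("K=", x$K_levels)))
  invisible(x)
}

#' @export
plot.alpha_curve <- function(x, ...) {
  graphics::plot(x$K_levels, x$alpha_hats, type = "b", pch = 19,
                 xlab = "aggregation level K",
                 ylab = expression(hat(alpha)),
                 ylim = range(c(x$alpha_hats, 2)), ...)
  graphics::abline(h = 2, lty = 2, col = "grey40")
  invisible(x)
}

#' Bootstrap replication of the alpha-vs-K curve
#'
#' Resamples the whole series with replacement \code{B} times (each resample
#' has the original length \code{N}), computes \code{\link{alpha_curve}} on
#' every resample, and summarizes each aggregation level with
#' \code{\link{boxplot_stats}}. Deterministic for a given seed.
#'
#' @param x numeric series.
#' @param B number of bootstrap replicates (default 100).
#' @param K_max number of aggregation levels (default 10).
#' @param seed optional integer for a deterministic resampling plan.
#' @param ... passed to \code{\link{estimate_stable}}.
#' @return An object of class \code{"alpha_bootstrap"}: list with \code{B},
#'   the \code{B x K_max} matrix \code{estimates}, \code{per_K_boxstats}
#'   (a list of \code{\link{boxplot_stats}} per level), \code{K_levels},
#'   \code{n} and \code{seed}.
#' @examples
#' bs <- bootstrap_curves(stable_rvs(600, stable_params(1.9, 1), seed = 1),
#'                        B = 5, K_max = 3, seed = 2)
#' @export
bootstrap_curves <- function(x, B = 100L, K_max = 10L, seed = NULL, ...) {
  x <- check_series(x, what = "x")
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != floor(B))
    stop("'B' must be a positive integer")
  n <- length(x)
  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  est <- matrix(NA_real_, nrow = B, ncol = K_max)
  for (b in seq_len(B))
    est[b, ] <- alpha_curve(x[idx[, b]], K_max = K_max, ...)$alpha_hats
  structure(list(B = as.integer(B), estimates = est,
                 per_K_boxstats = apply(est, 2L, boxplot_stats,
                                        simplify = FALSE),
                 K_levels = seq_len(K_max), n = n, seed = seed),
            class = "alpha_bootstrap")
}

#' @export
print.alpha_bootstrap <- function(x, ...) {
  cat("bootstrap alpha estimates:", x$B, "replicates x", length(x$K_levels),
      "aggregation levels (n =", x$n, ")\n")
  cat("per-K medians:\n")
  print(stats::setNames(round(apply(x$estimates, 2L, stats::median), 4),
                        paste0("K=", x$K_levels)))
  invisible(x)
}

#' Box-and-whisker plot of bootstrap alpha estimates per aggregation level
#'
#' @param x an \code{\link{bootstrap_curves}} result.
#' @param mean_curve if \code{TRUE}, draw the bootstrap-mean alpha curve
#'   instead of box plots (the recommended display for large datasets).
#' @param ... passed to the underlying plotting routine.
#' @export
plot.alpha_bootstrap <- function(x, mean_curve = FALSE, ...) {
  if (mean_curve) {
    m <- colMeans(x$estimates)
    graphics::plot(x$K_levels, m, type = "b", pch = 19,
                   xlab = "aggregation level K",
                   ylab = expression(paste("mean bootstrap ", hat(alpha))),
                   ylim = range(c(m, 2)), ...)
  } else {
    stats_mat <- vapply(x$per_K_boxstats, function(s)
      c(s$whisker_low, s$Q1, s$median, s$Q3, s$whisker_high), numeric(5))
    out <- unlist(lapply(x$per_K_boxstats, `[[`, "outliers"))
    grp <- rep(seq_along(x$per_K_boxstats),
               vapply(x$per_K_boxstats, function(s) length(s$outliers), 1L))
    graphics::bxp(list(stats = stats_mat, n = rep(x$B, length(x$K_levels)),
                       out = out, group = grp,
                       names = as.character(x$K_levels)),
                  xlab = "aggregation level K",
                  ylab = expression(hat(alpha)), ...)
  }
  graphics::abline(h = 2, lty = 2, col = "grey40")
  invisible(x)
}

#' Box-plot summary with the 1.5 IQR outlier rule
#'
#' Quartiles use linear interpolation between order statistics (the common
#' plotting-package default; \code{\link[stats]{quantile}} type 7). Points
#' are outliers exactly when they lie above \eqn{Q3 + 1.5(Q3 - Q1)} or below
#' \eqn{Q1 - 1.5(Q3 - Q1)}; the whiskers extend to the most extreme values
#' that are not outliers.
#'
#' @param values non-empty numeric vector.
#' @return An object of class \code{"boxplot_stats"}: list with \code{Q1},
#'   \code{median}, \code{Q3}, \code{whisker_low}, \code{whisker_high} and
#'   \code{outliers}.
#' @examples
#' boxplot_stats(c(1:9, 100))
#' @export
boxplot_stats <- function(values) {
  values <- check_series(values, what = "values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  is_out <- values < lo | values > hi
  structure(list(Q1 = q[1], median = q[2], Q3 = q[3],
                 whisker_low = min(values[!is_out]),
                 whisker_high = max(values[!is_out]),
                 outliers = values[is_out]),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "box-plot summary: [%.4g | %.4g (%.4g) %.4g | %.4g], %d outlier(s)\n",
    x$whisker_low, x$Q1, x$median, x$Q3, x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' Light- vs heavy-tailed verdict from an alpha-vs-K curve
#'
#' A documented numeric heuristic on top of the visual procedure: let
#' \eqn{m} be the median estimated index over the top three aggregation
#' levels. The verdict is \emph{light} (Gaussian domain of attraction) if
#' \eqn{m \ge 2 - \delta}; \emph{heavy} (non-Gaussian stable domain, with
#' \code{limiting_alpha = m}) if \eqn{m \le 2 - \delta} and the curve is not
#' still rising — its total drift (last minus first level) is below
#' \eqn{\delta}, or it has plateaued (the least-squares slope over the top
#' half of the levels, projected across that span, is below \eqn{\delta} in
#' magnitude); \emph{inconclusive} otherwise. This is a heuristic read-out,
#' not a calibrated hypothesis test.
#'
#' For a bootstrap result the per-level medians over replicates form the
#' curve, which suppresses most single-estimate noise.
#'
#' @param x an \code{\link{alpha_curve}} or \code{\link{bootstrap_curves}}
#'   result with at least 3 levels.
#' @param delta tolerance \eqn{\delta} on the distance from 2 (default 0.02).
#' @return An object of class \code{"tail_verdict"}: list with
#'   \code{domain_label} (\code{"light"}, \code{"heavy"} or
#'   \code{"inconclusive"}), \code{limiting_alpha}, and an \code{evidence}
#'   list tracing the rule.
#' @examples
#' cv <- alpha_curve(stable_rvs(2000, stable_params(1.9, 1), seed = 1))
#' classify_tails(cv)
#' @export
classify_tails <- function(x, delta = 0.02) UseMethod("classify_tails")

#' @rdname classify_tails
#' @export
classify_tails.alpha_curve <- function(x, delta = 0.02) {
  verdict_from_curve(x$alpha_hats, delta)
}

#' @rdname classify_tails
#' @export
classify_tails.alpha_bootstrap <- function(x, delta = 0.02) {
  verdict_from_curve(apply(x$estimates, 2L, stats::median), delta)
}

verdict_from_curve <- function(a, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("'delta' must be a single positive number")
  K <- length(a)
  if (K < 3L) stop("at least 3 aggregation levels are needed for a verdict")
  med_top <- stats::median(a[(K - 2L):K])
  drift <- a[K] - a[1L]
  top_half <- seq.int(K - ceiling(K / 2) + 1L, K)
  sl <- stats::cov(top_half, a[top_half]) / stats::var(top_half)
  plateau <- abs(sl * (length(top_half) - 1L)) < delta
  label <- if (med_top >= 2 - delta) "light"
  else if (drift < delta || plateau) "heavy"
  else "inconclusive"
  structure(list(
    domain_label = label,
    limiting_alpha = med_top,
    evidence = list(per_K = a, median_top3 = med_top, drift = drift,
                    plateau_slope = sl, plateau = plateau, delta = delta)
  ), class = "tail_verdict")
}

#' Do two tail verdicts disagree?
#'
#' Two verdicts are considered different when their domain labels differ, or
#' when both are heavy but their limiting stability indices are more than
#' \code{delta} apart (two heavy-tailed laws with distinct indices are
#' distinct laws — the aggregation curves plateau at different heights).
#'
#' @param a,b \code{\link{classify_tails}} results.
#' @param delta tolerance on the limiting index (default 0.02).
#' @return Logical.
#' @examples
#' x <- stable_rvs(2000, stable_params(1.85, 1), seed = 1)
#' y <- stable_rvs(2000, stable_params(1.9, 1), seed = 2)
#' verdicts_differ(classify_tails(alpha_curve(x)), classify_tails(alpha_curve(y)))
#' @export
verdicts_differ <- function(a, b, delta = 0.02) {
  if (!inherits(a, "tail_verdict") || !inherits(b, "tail_verdict"))
    stop("'a' and 'b' must be 'tail_verdict' objects")
  a$domain_label != b$domain_label ||
    (a$domain_label == "heavy" &&
       abs(a$limiting_alpha - b$limiting_alpha) > delta)
}

#' @export
print.tail_verdict <- function(x, ...) {
  cat(sprintf("tail verdict: %s (limiting alpha = %.4g)\n",
              x$domain_label, x$limiting_alpha))
  e <- x$evidence
  cat(sprintf(
    "  top-3 median = %.4g, drift = %.4g, plateau slope = %.4g, delta = %.3g\n",
    e$median_top3, e$drift, e$plateau_slope, e$delta))
  invisible(x)
}
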