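test_that("EDF steps, ties and brute-force counts agree", {
  f <- edf(5)
  expect_equal(f(4.9), 0)
  expect_equal(f(5), 1)
  expect_equal(edf(c(1, 1, 2))(1), 2 / 3)
  set.seed(81)
  x <- rnorm(200)
  f <- edf(x)
  for (t in c(-2, -0.3, 0, 0.4, 1.7))
    expect_equal(f(t), sum(x <= t) / length(x))
})

test_that("one-sample KS statistic and p-value are exact and calibrated", {
  # sample placed at exact quantile midpoints forces D = 0.5/n
  n <- 20
  x <- qnorm((seq_len(n) - 0.5) / n)
  r <- ks_one_sample(x, pnorm)
  expect_equal(unname(r$statistic), 0.5 / n)

  # agreement with the reference implementation (asymptotic mode)
  set.seed(82)
  y <- rnorm(500)
  mine <- ks_one_sample(y, pnorm)
  ref <- suppressWarnings(ks.test(y, pnorm, exact = FALSE))
  expect_equal(unname(mine$statistic), unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)

  # mass far in the tail drives D to 1
  expect_gt(unname(ks_one_sample(rnorm(50) + 100, pnorm)$statistic), 0.999)

  # p-values are uniform under the null: KS test on 500 seeded p-values
  set.seed(83)
  pv <- replicate(500, ks_one_sample(rnorm(200), pnorm)$p.value)
  expect_gt(suppressWarnings(ks.test(pv, punif))$p.value, 0.01)

  expect_error(ks_one_sample(y, function(q) q * 10), "outside")
})

test_that("two-sample KS matches jump-point enumeration and is symmetric", {
  r <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(unname(r$statistic), 1 / 3)

  set.seed(84)
  x <- rt(80, 3); y <- rnorm(120)
  expect_equal(unname(ks_two_sample(x, y)$statistic), brute_ks2(x, y))
  expect_equal(unname(ks_two_sample(x, y)$statistic),
               unname(ks_two_sample(y, x)$statistic))
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  expect_equal(unname(ks_two_sample(x, y)$statistic), unname(ref$statistic))
  expect_equal(ks_two_sample(x, y)$p.value, ref$p.value, tolerance = 1e-6)

  same <- ks_two_sample(x, x)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_equal(unname(ks_two_sample(1:5, 6:10)$statistic), 1)
})

test_that("normalization is exact, idempotent and affine-invariant", {
  z <- normalize_series(c(0, 2))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  x <- rexp(50)
  expect_equal(normalize_series(normalize_series(x)), normalize_series(x))
  expect_equal(normalize_series(3 * x + 7), normalize_series(x))
  expect_error(normalize_series(rep(1, 30)), "zero-variance")
})

test_that("Jarque-Bera statistic matches direct moments and holds its level", {
  # symmetric two-point sample: S = 0, Kurt = 1, JB = n/6
  x <- rep(c(-1, 1), 20)
  expect_equal(unname(jarque_bera(x)$statistic), 40 / 6)
  # shift/scale invariance
  set.seed(85)
  y <- rexp(100)
  expect_equal(unname(jarque_bera(5 * y - 3)$statistic),
               unname(jarque_bera(y)$statistic), tolerance = 1e-10)
  # nominal 5% level on Gaussian nulls, n = 2000
  set.seed(86)
  rej <- mean(replicate(500, jarque_bera(rnorm(2000))$p.value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # Monte-Carlo mode returns a grid p-value
  p <- jarque_bera(y, n_mc = 200, seed = 87)$p.value
  expect_equal(p * 200, round(p * 200))
  expect_error(jarque_bera(rnorm(10)), "at least 20")
})

test_that("stable CDF inversion matches the Gaussian branch and simulation", {
  # alpha = 2 reduces to the exact Gaussian CDF
  p2 <- stable_params(2, 1.3, 0, 0.5)
  q <- seq(-5, 5, by = 0.5)
  expect_equal(stable_cdf(q, p2), pnorm(q, 0.5, sqrt(2) * 1.3))

  # symmetric law: median at mu; CDF matches a large exact sample
  p <- stable_params(1.9, 1)
  expect_equal(stable_cdf(0, p), 0.5, tolerance = 1e-6)
  x <- stable_rvs(2e5, p, seed = 88)
  Fhat <- edf(x)
  qq <- c(-8, -3, -1, -0.25, 0.5, 2, 6)
  expect_lt(max(abs(stable_cdf(qq, p) - Fhat(qq))), 0.01)
  expect_true(all(diff(stable_cdf(seq(-50, 50, by = 0.5), p)) >= 0))
})

test_that("Anderson-Darling stable test holds its level on exact stable data", {
  ps <- vapply(1:3, function(s)
    ad_stable(stable_rvs(500, stable_params(1.9, 1), seed = 880 + s),
              n_boot = 200, seed = 890 + s)$p.value, numeric(1))
  expect_gte(sum(ps > 0.05), 2)
  # bootstrap p-values live on the grid 0, 1/n_boot, ..., 1
  expect_equal(ps * 200, round(ps * 200))
  expect_error(ad_stable(rep(4, 200), n_boot = 200), "zero variance")
  expect_error(ad_stable(rnorm(50)), "at least 100")
})
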