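test_that("block aggregation sums consecutive blocks and drops the remainder", {
  expect_equal(block_aggregate(c(1, 2, 3, 4, 5), 2), c(3, 7))
  x <- rnorm(57)
  expect_identical(block_aggregate(x, 1), x)
  for (K in c(2, 3, 5, 10)) {
    agg <- block_aggregate(x, K)
    m <- length(x) %/% K
    expect_length(agg, m)
    # conservation: the block sums account exactly for the leading K*m values
    expect_equal(sum(agg), sum(x[seq_len(K * m)]))
    # spot-check one interior block against a hand-built sum
    expect_equal(agg[2], sum(x[(K + 1):(2 * K)]))
  }
  expect_error(block_aggregate(x, 58), "exceeds")
  expect_error(block_aggregate(x, 0), "positive integer")
})

test_that("alpha curve is flat for exact stable data", {
  flat <- vapply(1:5, function(s) {
    ac <- alpha_curve(stable_rvs(2000, stable_params(1.9, 1), seed = s))
    diff(range(ac$alpha_hats)) < 0.1
  }, logical(1))
  expect_gte(sum(flat), 3)
})

test_that("aggregation leaves the index of exact stable data untilted", {
  # average least-squares slope of the curve across seeds stays an order of
  # magnitude below the 0.1 visual flatness criterion per level
  set.seed(71)
  for (a in c(1.85, 1.95)) {
    slopes <- replicate(60, {
      ah <- alpha_curve(stable_rvs(2000, stable_params(a, 1)))$alpha_hats
      unname(coef(lm(ah ~ seq_along(ah)))[2])
    })
    expect_lt(abs(mean(slopes)), 0.003)
  }
})

test_that("alpha curve validates its inputs and labels failures with K", {
  expect_error(alpha_curve(rnorm(300), K_max = 10), "minimum length")
  expect_error(alpha_curve(rep(2, 2000), K_max = 10), "K = 1")
})

test_that("box-plot summaries match the brute-force quartile/fence rule", {
  b <- boxplot_stats(c(1:9, 100))
  expect_equal(b$outliers, 100)
  expect_equal(b$whisker_high, 9)

  b2 <- boxplot_stats(rep(3.7, 12))
  expect_equal(unlist(b2[c("Q1", "median", "Q3", "whisker_low", "whisker_high")]),
               rep(3.7, 5), ignore_attr = TRUE)
  expect_length(b2$outliers, 0)

  set.seed(72)
  for (i in 1:50) {
    v <- rt(sample(5:60, 1), df = 2)
    got <- boxplot_stats(v)
    want <- brute_box(v)
    expect_equal(got$Q1, want$Q1)
    expect_equal(got$Q3, want$Q3)
    expect_equal(sort(got$outliers), sort(want$outliers))
    expect_equal(got$whisker_low, want$whisker_low)
    expect_equal(got$whisker_high, want$whisker_high)
    # partition: outliers plus non-outliers recover the input multiset
    expect_equal(sort(c(got$outliers,
                        v[v >= got$whisker_low & v <= got$whisker_high])),
                 sort(v))
    expect_true(got$Q1 <= got$median && got$median <= got$Q3)
  }
})

test_that("bootstrap curves are deterministic and widen with K", {
  x <- stable_rvs(2000, stable_params(1.85, 1), seed = 73)
  b1 <- bootstrap_curves(x, B = 30, K_max = 5, seed = 99)
  b2 <- bootstrap_curves(x, B = 30, K_max = 5, seed = 99)
  expect_identical(b1$estimates, b2$estimates)

  # B = 1: all five box summaries collapse onto the single replicate
  b0 <- bootstrap_curves(x, B = 1, K_max = 3, seed = 1)
  s <- b0$per_K_boxstats[[1]]
  expect_equal(s$Q1, s$median)
  expect_equal(s$median, s$Q3)
  expect_equal(s$whisker_low, s$whisker_high)

  # dispersion grows with K: the estimation runs on shorter samples
  bs <- bootstrap_curves(x, B = 100, K_max = 10, seed = 74)
  iqrs <- vapply(bs$per_K_boxstats, function(s) s$Q3 - s$Q1, numeric(1))
  trend <- unname(coef(lm(iqrs ~ seq_along(iqrs)))[2])
  expect_gt(trend, 0)
  expect_gt(iqrs[10], iqrs[1])
})

test_that("the verdict rule is forced on clean curves", {
  v <- classify_tails(fake_curve(rep(2, 10)))
  expect_equal(v$domain_label, "light")
  expect_equal(v$limiting_alpha, 2)

  v <- classify_tails(fake_curve(rep(1.90, 10)))
  expect_equal(v$domain_label, "heavy")
  expect_equal(v$limiting_alpha, 1.90)

  # rising curve that has reached the 2 - delta band over the top levels
  v <- classify_tails(fake_curve(c(1.85, 1.88, 1.91, 1.94, 1.96, 1.97,
                                   1.98, 1.985, 1.99, 1.99)))
  expect_equal(v$domain_label, "light")

  # rising but still far from 2: not yet classifiable
  v <- classify_tails(fake_curve(seq(1.5, 1.8, length.out = 10)))
  expect_equal(v$domain_label, "inconclusive")

  expect_error(classify_tails(fake_curve(c(1.9, 1.9))), "at least 3")
  expect_error(classify_tails(fake_curve(rep(1.9, 10)), delta = 0), "positive")
})

test_that("verdict disagreement covers labels and distinct heavy plateaus", {
  va <- classify_tails(fake_curve(rep(1.85, 10)))
  vb <- classify_tails(fake_curve(rep(1.90, 10)))
  vl <- classify_tails(fake_curve(rep(2, 10)))
  expect_true(verdicts_differ(va, vl))
  expect_true(verdicts_differ(va, vb))    # both heavy, plateaus 0.05 apart
  expect_false(verdicts_differ(va, va))
  expect_false(verdicts_differ(vl, vl))
})
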