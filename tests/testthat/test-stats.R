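test_that("sign test: exact binomial p for small samples", {
  # 10 values all above the null: p = 2 * 0.5^10
  out <- sign_test(rep(1.2, 10), null = 1)
  expect_equal(out$p_value, 2 * 0.5^10)
  expect_equal(out$statistic_name, "k")
  # symmetric 3/3 split: p = 1
  expect_equal(sign_test(c(1.1, 1.2, 1.3, 0.7, 0.8, 0.9))$p_value, 1)
})

test_that("sign test: ties with the null are dropped and counted", {
  out <- sign_test(c(1, 1, 1.2, 1.3, 0.8), null = 1)
  expect_equal(out$ties_dropped, 2L)
  expect_equal(out$n, 3L)
  expect_error(sign_test(c(1, 1, 1), null = 1), "degenerate")
})

test_that("sign test: large-sample Z matches the continuity-corrected oracle", {
  n <- 162
  for (k in c(0, 40, 81, 90, 105, 162)) {
    vals <- c(rep(1.5, k), rep(0.5, n - k))
    out <- sign_test(vals, null = 1)
    expect_equal(out$statistic_name, "Z")
    expect_equal(out$statistic, oracle_sign_z(k, n))
    expect_equal(out$p_value, min(1, 2 * pnorm(-abs(oracle_sign_z(k, n)))))
  }
})

test_that("exact and approximate sign-test p agree near the n = 100 boundary", {
  # agreement is asserted over the practically relevant range |Z| <~ 3
  # (p down to ~0.002); deeper in the tail the relative error of any normal
  # approximation necessarily diverges
  for (n in 90:100) {
    for (k in (n %/% 2 + 1):(n %/% 2 + 15)) {
      exact <- oracle_sign_p(k, n)
      approx <- min(1, 2 * pnorm(-abs(oracle_sign_z(k, n))))
      expect_lt(abs(approx - exact) / exact, 0.10)
    }
  }
})

test_that("K-S d statistic matches hand cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "at least one")
})

test_that("K-S d is invariant under common monotone transforms", {
  set.seed(20)
  a <- rnorm(40, 1)
  b <- rnorm(60, 1.4)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(exp(a), exp(b))$statistic, d0)
  expect_equal(ks_two_sample(a^3, b^3)$statistic, d0)
})

test_that("one-sample t matches the brute-force formula", {
  x <- c(90, 110, 120, 100, 95)
  out <- one_sample_t(x, mu = 100)
  want <- (mean(x) - 100) / (sd(x) / sqrt(5))
  expect_equal(out$statistic, want)
  expect_equal(out$df, 4)
  # mean exactly at the null: t = 0, p = 1
  zero <- one_sample_t(c(1, 2, 3), mu = 2)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)
  expect_error(one_sample_t(c(5, 5, 5), mu = 4), "zero variance")
})

test_that("pooled two-sample t reports n1 + n2 - 2 degrees of freedom", {
  set.seed(21)
  out <- two_sample_t(rnorm(5, 110, 10), rnorm(5, 100, 10))
  expect_equal(out$df, 8)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.03, m = 2), 0.06)
  expect_equal(bonferroni(0.8, m = 2), 1)
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_error(bonferroni(0.5, m = 0), "m")
  expect_error(bonferroni(1.2, m = 2), "p")
})

test_that("sign-test type-I error is near alpha for symmetric FI-like data", {
  set.seed(22)
  rejections <- vapply(1:400, function(i) {
    x <- exp(rnorm(60, 0, 0.2))  # median exactly 1
    sign_test(x, null = 1)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.09)
})
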