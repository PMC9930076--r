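test_that("paired t matches the hand-computed oracle", {
  res <- pairedT(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res@statistic, -4, tolerance = 1e-12)
  expect_equal(res@df, 2)
  expect_equal(res@effect_size, -sqrt(16 / 18), tolerance = 1e-12)
  expect_identical(res@method, "paired_t")
  expect_error(pairedT(1:5, 1:5), "degenerate differences")
  expect_error(pairedT(1:4, 1:5), "paired")
})

test_that("paired t p-value agrees with a sign-flip permutation oracle", {
  set.seed(41)
  x <- rnorm(9, 0.6); y <- rnorm(9)
  d <- x - y
  tstat <- function(d) mean(d) / (sd(d) / sqrt(length(d)))
  t_obs <- abs(tstat(d))
  # full enumeration of the 2^9 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 9)))
  t_perm <- apply(signs, 1, function(s) abs(tstat(d * s)))
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  res <- pairedT(x, y)
  expect_lt(abs(res@p_value - p_perm), 0.05)
})

test_that("parametric p-values match a numeric t-CDF oracle", {
  dens <- function(u, df) gamma((df + 1) / 2) / (sqrt(df * pi) *
    gamma(df / 2)) * (1 + u^2 / df)^(-(df + 1) / 2)
  for (case in list(c(1.3, 7), c(2.6, 12), c(0.4, 31))) {
    t0 <- case[1]; df <- case[2]
    tail <- stats::integrate(dens, t0, Inf, df = df,
                             rel.tol = 1e-10)$value
    expect_equal(2 * pt(-t0, df), 2 * tail, tolerance = 1e-6)
  }
})

test_that("independent t routes by Levene and matches summaries", {
  set.seed(42)
  x <- rnorm(14, 10, 2); y <- rnorm(19, 12, 2)
  auto <- independentT(x, y)
  expect_true(auto@method %in% c("pooled_t", "welch_t"))
  expect_s4_class(auto@details$levene, "StatTestResult")
  frm <- tFromSummary(mean(x), sd(x), 14, mean(y), sd(y), 19,
                      method = if (auto@method == "pooled_t") "pooled"
                               else "welch")
  expect_equal(auto@statistic, frm@statistic, tolerance = 1e-10)
  expect_equal(auto@df, frm@df, tolerance = 1e-10)

  same <- independentT(x, x, variance_policy = "pooled")
  expect_equal(same@statistic, 0)
  expect_equal(same@effect_size, 0)
})

test_that("pooled and Welch t coincide for equal n and equal SD", {
  set.seed(43)
  x <- rnorm(10)
  y <- x + 2  # identical spread, shifted
  p <- independentT(x, y, variance_policy = "pooled")
  w <- independentT(x, y, variance_policy = "welch")
  expect_equal(p@statistic, w@statistic, tolerance = 1e-12)
  expect_equal(p@df, w@df, tolerance = 1e-12)
})

test_that("Welch df always lies within its theoretical bounds", {
  set.seed(44)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 4))
    y <- rnorm(n2, sd = runif(1, 0.5, 4))
    res <- independentT(x, y, variance_policy = "welch")
    expect_gte(res@df, min(n1, n2) - 1 - 1e-9)
    expect_lte(res@df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("summary-statistic t reproduces the published cohort rows", {
  age <- tFromSummary(48.6, 12.4, 14, 58.1, 15.7, 19, method = "pooled")
  expect_equal(round(age@statistic, 1), -1.9)
  expect_equal(age@df, 31)
  expect_equal(round(age@effect_size, 1), -0.3)

  exper <- tFromSummary(3.1, 2.8, 14, 29.4, 19.8, 19, method = "welch")
  expect_equal(round(exper@statistic, 1), -5.7)
  expect_true(exper@significant)

  eq <- tFromSummary(5, 1, 10, 5, 2, 12)
  expect_equal(eq@statistic, 0)
  expect_error(tFromSummary(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("Mann-Whitney matches the hand oracle and its invariants", {
  res <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(res@statistic, 0)
  expect_equal(res@details$z, -2 / sqrt(4 * 5 / 12), tolerance = 1e-6)
  expect_equal(round(res@details$z, 3), -1.549)
  expect_equal(round(res@effect_size, 3), -0.775)

  # same multiset in both groups: centre of the U distribution
  same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@details$z, 0)
  expect_equal(same@effect_size, 0)
  expect_error(mannWhitney(rep(2, 4), rep(2, 5)), "degenerate")
})

test_that("U + U' = n1*n2 and U is invariant to monotone transforms", {
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(sample(4:10, 1)); y <- rnorm(sample(4:10, 1))
    r1 <- mannWhitney(x, y)
    expect_equal(r1@details$U1 + r1@details$U2,
                 length(x) * length(y))
    r2 <- mannWhitney(exp(x), exp(y))   # strictly increasing transform
    expect_equal(r1@statistic, r2@statistic)
    expect_equal(r1@details$z, r2@details$z, tolerance = 1e-12)
  }
})

test_that("the normal-approximation p is close to the exact p at small n", {
  # without a continuity correction the approximation sits within ~0.05 of
  # the exact rank-permutation p at n1 = 7, n2 = 8
  set.seed(46)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(8, 0.5)
    res <- mannWhitney(x, y)
    exact <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(res@p_value - exact), 0.05)
  }
})

test_that("chi-squared reproduces the published 2x2 row and closed form", {
  side <- chiSquared(matrix(c(9, 13, 5, 6), 2))
  expect_equal(round(side@statistic, 1), 0.1)
  expect_equal(side@df, 1)
  expect_equal(round(side@p_value, 2), 0.80)
  expect_equal(round(side@effect_size, 1), 0.0)

  set.seed(47)
  for (i in 1:10) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
    N <- sum(m)
    closed <- N * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    res <- chiSquared(m)
    expect_equal(res@statistic, closed, tolerance = 1e-10)
    # permutation invariance
    expect_equal(chiSquared(m[, 2:1])@statistic, res@statistic,
                 tolerance = 1e-12)
    expect_equal(chiSquared(m[2:1, ])@statistic, res@statistic,
                 tolerance = 1e-12)
    expect_gte(res@effect_size, 0)
    expect_lte(res@effect_size, 1)
  }

  prop <- matrix(c(10, 20, 5, 10), 2)  # identical row proportions
  expect_equal(chiSquared(prop)@statistic, 0, tolerance = 1e-12)
  expect_error(chiSquared(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate table")

  yates <- chiSquared(matrix(c(9, 13, 5, 6), 2), correction = "yates")
  expect_equal(yates@statistic,
               unname(suppressWarnings(
                 chisq.test(matrix(c(9, 13, 5, 6), 2),
                            correct = TRUE))$statistic))
})

test_that("normality check routes by Shapiro-Wilk", {
  set.seed(48)
  normal <- rnorm(100)
  skewed <- exp(rnorm(100))
  expect_true(checkNormality(normal)$parametric)
  expect_false(checkNormality(skewed)$parametric)
  chk <- checkNormality(normal)
  expect_s4_class(chk$shapiro, "StatTestResult")
  expect_s4_class(chk$ks, "StatTestResult")
  expect_error(checkNormality(c(1, 2)), "too small")
  expect_error(checkNormality(rep(1, 10)), "too small|degenerate")
})
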