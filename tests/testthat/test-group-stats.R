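# Group statistics: pooled t, 2x2 chi-square, Pearson, Kendall tau-b, ANCOVA.

test_that("identical group summaries give t = 0, p = 1", {
  r <- twoSampleTFromSummary(52, 10, 14, 52, 10, 14)
  expect_equal(statistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_equal(r@df, 26)
})

test_that("summary t matches a quadrature oracle for the t density", {
  r <- twoSampleTFromSummary(28.4, 1.3, 14, 28.1, 1.1, 14)
  # independent p: numerically integrate the t density beyond |t|
  tdens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(tdens, abs(statistic(r)), Inf, df = 26,
                    rel.tol = 1e-10)$value
  expect_equal(pValue(r), 2 * tail, tolerance = 1e-8)
  # and the raw-data overload agrees with base R's pooled t test
  set.seed(60)
  x <- rnorm(14, 28.4, 1.3); y <- rnorm(14, 28.1, 1.1)
  raw <- twoSampleT(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(statistic(raw), unname(tt$statistic))
  expect_equal(pValue(raw), tt$p.value)
})

test_that("degenerate t inputs follow the documented conventions", {
  expect_error(twoSampleTFromSummary(1, 0, 1, 2, 1, 14), "n >= 2")
  expect_equal(pValue(twoSampleTFromSummary(5, 0, 5, 5, 0, 5)), 1)
  expect_equal(pValue(twoSampleTFromSummary(5, 0, 5, 6, 0, 5)), 0)
  expect_equal(pValue(twoSampleT(rep(3, 4), rep(3, 5))), 1)
})

test_that("2x2 chi-square: closed form, zero marginals, invariances", {
  r <- chiSquare2x2(matrix(c(11, 4, 3, 10), 2, 2))
  expect_equal(statistic(r), 28 * (11 * 10 - 3 * 4)^2 / (14 * 14 * 15 * 13))
  # cross-check against the standard uncorrected test
  ct <- chisq.test(matrix(c(11, 4, 3, 10), 2, 2), correct = FALSE)
  expect_equal(statistic(r), unname(ct$statistic))
  expect_equal(pValue(r), ct$p.value)
  # proportional rows: statistic exactly 0
  expect_equal(statistic(chiSquare2x2(matrix(c(6, 3, 4, 2), 2, 2))), 0)
  # zero marginal convention
  z <- chiSquare2x2(matrix(c(0, 0, 5, 7), 2, 2))
  expect_equal(statistic(z), 0)
  expect_equal(pValue(z), 1)
  # invariant to transpose and to consistent row/column swaps
  tab <- matrix(c(9, 2, 5, 12), 2, 2)
  expect_equal(statistic(chiSquare2x2(tab)), statistic(chiSquare2x2(t(tab))))
  expect_equal(statistic(chiSquare2x2(tab)),
               statistic(chiSquare2x2(tab[2:1, 2:1])))
  expect_error(chiSquare2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("pearson correlation: exact cases and summation oracle", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(estimate(pearsonR(x, 2 * x + 1)), 1)
  expect_equal(estimate(pearsonR(x, -x)), -1)
  set.seed(61)
  a <- rnorm(8); b <- rnorm(8)
  r <- pearsonR(a, b)
  # independent summation oracle: covariance / product of SDs
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(estimate(r), num / den, tolerance = 1e-12)
  expect_equal(r@df, 6)
  expect_error(pearsonR(rep(1, 5), rnorm(5)), "constant")
})

test_that("kendall tau-b: exact cases and pair-enumeration oracle with ties", {
  expect_equal(estimate(kendallTauB(1:6, c(2, 3, 5, 8, 9, 11))), 1)
  expect_equal(estimate(kendallTauB(1:6, 6:1)), -1)
  x <- c(1, 2, 2, 3, 4, 4, 5)
  y <- c(2, 2, 3, 1, 5, 6, 6)
  expect_equal(estimate(kendallTauB(x, y)), tauBOracle(x, y),
               tolerance = 1e-12)
  set.seed(62)
  for (i in 1:5) {
    a <- sample(1:5, 10, replace = TRUE)
    b <- sample(1:5, 10, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(estimate(kendallTauB(a, b)), tauBOracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(kendallTauB(rep(2, 5), 1:5), "tied")
})

test_that("ANCOVA reduces to the t test when the covariate is orthogonal", {
  # covariate identical across groups (mirrored), so adjustment changes
  # nothing about the group contrast
  dep <- c(1.2, 0.8, 1.1, 0.9, 2.0, 1.6, 1.9, 1.7)
  grp <- rep(c("A", "B"), each = 4)
  cov <- c(1, 2, 3, 4, 1, 2, 3, 4)
  a <- ancovaGroup(dep, grp, cov)
  tt <- t.test(dep[grp == "B"], dep[grp == "A"], var.equal = TRUE)
  # same group effect; p differs only through the residual df spent on the
  # covariate, so compare the estimate and the normal-equations solution
  expect_equal(estimate(a), unname(diff(tapply(dep, grp, mean))),
               tolerance = 1e-9)
  X <- cbind(1, grp == "B", cov)
  beta <- solve(t(X) %*% X, t(X) %*% dep)
  expect_equal(estimate(a), beta[2], tolerance = 1e-12)
})

test_that("ANCOVA recovers planted effects within Monte-Carlo error", {
  set.seed(63)
  delta <- 0.5; beta <- 0.3
  ests <- t(replicate(100, {
    grp <- rep(0:1, each = 14)
    cov <- rnorm(28)
    dep <- delta * grp + beta * cov + rnorm(28, sd = 0.4)
    a <- ancovaGroup(dep, grp, cov)
    fit <- lm(dep ~ grp + cov)
    c(estimate(a), coef(fit)[["cov"]])
  }))
  seD <- sd(ests[, 1]) / sqrt(100)
  seB <- sd(ests[, 2]) / sqrt(100)
  expect_lt(abs(mean(ests[, 1]) - delta), 3 * seD)
  expect_lt(abs(mean(ests[, 2]) - beta), 3 * seB)
  expect_error(ancovaGroup(rnorm(10), rep("A", 10), rnorm(10)), "two levels")
  expect_error(ancovaGroup(rnorm(10), rep(c("A", "B"), 5), rep(1, 10)),
               "constant")
})
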