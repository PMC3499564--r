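# Diagnostics against naive / closed-form oracles.

test_that("gammaAutocovariance matches a naive double loop", {
  set.seed(41)
  g <- matrix(rbinom(300, 1, 0.4), 100, 3)
  for (lag in c(0L, 1L, 3L)) {
    mu <- colMeans(g)
    N <- nrow(g)
    naive <- 0
    for (j in 1:3) for (t in 1:(N - lag))
      naive <- naive + (g[t, j] - mu[j]) * (g[t + lag, j] - mu[j])
    expect_equal(gammaAutocovariance(g, lag), naive / (N - lag),
                 tolerance = 1e-12)
  }
  expect_error(gammaAutocovariance(g, -1), "nonnegative")
})

test_that("jump-distance identity: E[hamming] ~ 2 (V - cov1)", {
  set.seed(42)
  # a reversible 2-state-per-coordinate chain with known autocovariance
  N <- 20000; m <- 3
  g <- matrix(0L, N, m)
  g[1, ] <- rbinom(m, 1, 0.5)
  for (t in 2:N) {
    flip <- runif(m) < 0.2
    g[t, ] <- ifelse(flip, 1L - g[t - 1, ], g[t - 1, ])
  }
  ham <- mean(rowSums(abs(diff(g))))
  v0 <- gammaAutocovariance(g, 0); v1 <- gammaAutocovariance(g, 1)
  expect_equal(ham, 2 * (v0 - v1), tolerance = 0.05)
})

test_that("geyerEss is calibrated on white noise and AR(1)", {
  set.seed(43)
  wn <- rnorm(20000)
  r <- geyerEss(wn)
  expect_gte(r$ess / 20000, 0.8)
  expect_lte(r$ess / 20000, 1.2)
  phi <- 0.8
  x <- as.numeric(arima.sim(list(ar = phi), 50000))
  act <- geyerEss(x)$act
  expect_lt(abs(act - (1 + phi) / (1 - phi)) / ((1 + phi) / (1 - phi)), 0.2)
  expect_warning(rc <- geyerEss(rep(1, 100)), "zero-variance")
  expect_equal(rc$ess, 100)
  expect_error(geyerEss(1:5), "at least 10")
})

test_that("psrf behaves at its fixed points", {
  set.seed(44)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_lt(psrf(list(a, b)), 1.05)
  expect_gt(psrf(list(a, b + 10)), 3)
  expect_equal(psrf(list(rep(2, 50), rep(2, 50))), 1)
  expect_error(psrf(list(a)), "at least 2")
  expect_error(psrf(list(a, b[-1])), "equal length")
})

test_that("moveStatistics are plain arithmetic means", {
  mr <- data.frame(jump = c(0L, 2L, 1L, 0L), kProposed = c(1L, 2L, 1L, 4L))
  s <- moveStatistics(mr)
  expect_equal(s$rjd, 0.75)
  expect_equal(s$pjd, 2)
  expect_equal(s$rjdOverPjd, 0.375)
  expect_equal(s$moveRate, 0.5)
  expect_error(moveStatistics(mr[0, ]), "non-empty")
})

test_that("modelGof accepts the true law and rejects a wrong one", {
  set.seed(45)
  p <- c(0.4, 0.3, 0.2, 0.1)
  draws <- sample(0:3, 20000, TRUE, p)
  expect_gt(modelGof(draws, p)$pValue, 0.01)
  expect_lt(modelGof(draws, rev(p))$pValue, 1e-6)
  # ESS rescaling shrinks the statistic proportionally
  g1 <- modelGof(draws, p, ess = 20000)
  g2 <- modelGof(draws, p, ess = 2000)
  expect_equal(g2$statistic, g1$statistic / 10, tolerance = 1e-8)
})

test_that("gammaCodes encodes bit positions", {
  expect_identical(gammaCodes(rbind(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))),
                   c(1L, 6L, 7L))
  expect_error(gammaCodes(matrix(0, 2, 26)), "m <= 25")
})
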