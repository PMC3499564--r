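# Rao-Blackwellized conditionals against numerical quadrature, the
# expected-jump-distance objective against exact expectations, and the
# finite-adaptation freeze contract.

test_that("rbConditionalPip matches quadrature over the effect size", {
  set.seed(31)
  X <- matrix(rbinom(80, 2, 0.35), 20, 4)
  y <- rnorm(20, X[, 2] * 0.8)
  gd <- gwasData(X, y)
  prior <- priorSpec(aPi = 1, bPi = 5)
  gamma <- c(FALSE, TRUE, FALSE, FALSE)
  beta <- c(0, 0.6, 0, 0)
  sigma2 <- 0.9
  tau2 <- c(0.2, 0.3, 0.15, 0.25)
  got <- rbConditionalPip(gd, prior, gamma, beta, sigma2, tau2)
  m <- 4
  for (j in 1:m) {
    # residual with j's own contribution restored
    r <- gd@y - as.vector(gd@X %*% beta) + gd@X[, j] * beta[j]
    xj <- gd@X[, j]
    lik1 <- integrate(function(b) vapply(b, function(bb)
      exp(sum(dnorm(r, xj * bb, sqrt(sigma2), log = TRUE)) +
            dnorm(bb, 0, sqrt(sigma2 * tau2[j]), log = TRUE) + 60),
      numeric(1)), -5, 5, rel.tol = 1e-10)$value
    lik0 <- exp(sum(dnorm(r, 0, sqrt(sigma2), log = TRUE)) + 60)
    qMinus <- sum(gamma) - gamma[j]
    odds <- (lik1 / lik0) * (prior@aPi + qMinus) /
      (prior@bPi + m - 1 - qMinus)
    expect_equal(got[j], odds / (1 + odds), tolerance = 1e-6)
  }
})

test_that("ejdObjective is exact on single-parameter histories", {
  h <- list(k = c(1, 2, 1, 3), a = c(1, 0.5, 1, 0.2),
            pUsed = rep(0.5, 4))
  # candidate equal to the sampling parameter: weights are 1, so the
  # objective is the plain average of k * a
  expect_equal(ejdObjective(h, 0.5), mean(h$k * h$a), tolerance = 1e-12)
  expect_error(ejdObjective(list(k = numeric(0)), 0.5), "non-empty")
})

test_that("ejdObjective recovers the exact expectation by importance sampling", {
  set.seed(32)
  kMax <- 10L
  aLaw <- function(k) 0.85^k
  # pooled history drawn under two parameters
  drawK <- function(p, N) {
    pmf <- truncGeomPmf(1:kMax, p, kMax)
    sample.int(kMax, N, replace = TRUE, prob = pmf)
  }
  k <- c(drawK(0.3, 4000), drawK(0.7, 4000))
  h <- list(k = k, a = aLaw(k), pUsed = rep(c(0.3, 0.7), each = 4000))
  for (pc in c(0.2, 0.5, 0.8)) {
    exact <- sum((1:kMax) * aLaw(1:kMax) * truncGeomPmf(1:kMax, pc, kMax))
    expect_equal(ejdObjective(h, pc, kMax), exact, tolerance = 0.05)
  }
})

test_that("adaptMoveSize lands on the brute-force maximizer", {
  set.seed(33)
  kMax <- 20L
  grid <- seq(0.05, 0.95, by = 0.05)
  aLaw <- function(k) 0.8^k
  pmf5 <- truncGeomPmf(1:kMax, 0.5, kMax)
  k <- sample.int(kMax, 20000, replace = TRUE, prob = pmf5)
  h <- list(k = k, a = aLaw(k), pUsed = rep(0.5, length(k)))
  exactObj <- vapply(grid, function(p)
    sum((1:kMax) * aLaw(1:kMax) * truncGeomPmf(1:kMax, p, kMax)),
    numeric(1))
  best <- grid[which.max(exactObj)]
  expect_lte(abs(adaptMoveSize(h, grid, kMax) - best), 0.05 + 1e-9)
})

test_that("weight adaptation refuses to run after the freeze", {
  ps <- SpikeSlabGWAS:::.proposalStateNew(5)
  SpikeSlabGWAS:::.adaptWeights(ps, rep(0.4, 5))
  expect_equal(ps$addW, rep(0.4, 5))
  ps$frozen <- TRUE
  expect_error(SpikeSlabGWAS:::.adaptWeights(ps, rep(0.4, 5)), "freeze")
})

test_that("the RB running mean includes its warm start", {
  est <- SpikeSlabGWAS:::.rbEstimatorNew(3, 1, 3)
  expect_equal(est$pipHat, rep(0.25, 3))
  SpikeSlabGWAS:::.rbUpdate(est, c(1, 0, 0.5))
  expect_equal(est$pipHat, (rep(0.25, 3) + c(1, 0, 0.5)) / 2)
})
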