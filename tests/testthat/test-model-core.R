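# Closed-form prior and marginal likelihood against independent dense
# computations, and the incremental state against fresh refactorization.

makeData <- function(n, m, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]),
              n, m)
  y <- rnorm(n)
  gwasData(X, y)
}

test_that("logPriorGamma matches the integrated Bernoulli-beta form", {
  m <- 12; aPi <- 1.5; bPi <- 7
  # integrate P(gamma | pi) pi^(a-1)(1-pi)^(b-1)/B(a,b) numerically
  for (q in c(0L, 1L, 5L, 12L)) {
    direct <- integrate(function(p)
      p^(q + aPi - 1) * (1 - p)^(m - q + bPi - 1), 0, 1,
      rel.tol = 1e-12)$value / beta(aPi, bPi)
    expect_equal(logPriorGamma(q, m, aPi, bPi), log(direct),
                 tolerance = 1e-9)
  }
  expect_error(logPriorGamma(-1, m, 1, 1), "q must lie")
  expect_error(logPriorGamma(13, m, 1, 1), "q must lie")
})

test_that("logMarginalLikelihood matches the dense n x n Student form", {
  gd <- makeData(25, 6, seed = 2)
  prior <- priorSpec(nuSigma = 2, s2Sigma = 0.8)
  n <- nSamples(gd)
  for (incl in list(integer(0), 2L, c(1L, 4L), c(2L, 3L, 5L, 6L))) {
    tau2 <- runif(length(incl), 0.05, 0.5)
    got <- logMarginalLikelihood(gd, prior, incl, tau2)
    # independent path: multivariate-t density via the n x n matrix
    # M = I + X_g D X_g', using det(M) and y' M^{-1} y directly
    Xg <- gd@X[, incl, drop = FALSE]
    M <- diag(n) + Xg %*% (tau2 * t(Xg))
    S <- drop(crossprod(gd@y, solve(M, gd@y)))
    const <- lgamma((prior@nuSigma + n - 1) / 2) - lgamma(prior@nuSigma / 2) -
      ((n - 1) / 2) * log(pi * prior@nuSigma * prior@s2Sigma)
    want <- const - 0.5 * determinant(M)$modulus[1] -
      (prior@nuSigma + n - 1) / 2 *
      log1p(S / (prior@nuSigma * prior@s2Sigma))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("saturated models are rejected", {
  gd <- makeData(6, 8, seed = 3)
  expect_error(logMarginalLikelihood(gd, priorSpec(), 1:5, rep(0.2, 5)),
               "saturated")
})

test_that("incremental state tracks dense recomputation through a walk", {
  gd <- makeData(30, 10, seed = 4)
  prior <- priorSpec()
  st <- SpikeSlabGWAS:::.stateNew(gd, prior)
  tau2full <- runif(10, 0.05, 0.4)
  SpikeSlabGWAS:::.stateSetTau2(st, tau2full)
  set.seed(11)
  for (step in 1:150) {
    j <- sample.int(10, 1)
    if (st$inModel[j]) SpikeSlabGWAS:::.stateRemove(st, j)
    else SpikeSlabGWAS:::.stateAdd(st, j, tau2full[j])
    dense <- logMarginalLikelihood(gd, prior, st$incl,
                                   tau2full[st$incl]) +
      logPriorGamma(st$q, 10, prior@aPi, prior@bPi)
    expect_equal(st$logpost, dense, tolerance = 1e-8)
  }
})

test_that("collinear additions are refused with a warning", {
  set.seed(5)
  X <- matrix(rbinom(40, 2, 0.4), 20, 2)
  X <- cbind(X, X[, 1])  # exact duplicate column
  gd <- gwasData(X, rnorm(20))
  st <- SpikeSlabGWAS:::.stateNew(gd, priorSpec())
  # huge tau2 makes the prior ridge negligible, exposing the singularity
  expect_true(SpikeSlabGWAS:::.stateAdd(st, 1L, 1e14))
  expect_warning(ok <- SpikeSlabGWAS:::.stateAdd(st, 3L, 1e14),
                 "non-positive pivot")
  expect_false(ok)
  expect_equal(st$q, 1L)  # state unchanged by the refused add
})

test_that("saturation guard declines silently", {
  gd <- makeData(6, 8, seed = 6)
  st <- SpikeSlabGWAS:::.stateNew(gd, priorSpec())
  for (j in 1:4) SpikeSlabGWAS:::.stateAdd(st, j, 0.3)
  expect_equal(st$q, 4L)  # n - 2 = 4
  expect_false(SpikeSlabGWAS:::.stateAdd(st, 5L, 0.3))
})

test_that("enumeratePosterior is a proper distribution with consistent PIPs", {
  gd <- makeData(30, 5, seed = 7)
  enum <- enumeratePosterior(gd, priorSpec(), tau2 = 0.3)
  expect_equal(sum(enum$prob), 1, tolerance = 1e-12)
  expect_equal(sum(enum$sizeProb), 1, tolerance = 1e-12)
  # pip_j = sum of prob over models containing j
  pipManual <- vapply(1:5, function(j)
    sum(enum$prob[vapply(enum$models, function(md) j %in% md, logical(1))]),
    numeric(1))
  expect_equal(enum$pip, pipManual, tolerance = 1e-12)
  big <- gwasData(matrix(rbinom(25 * 21, 2, 0.4), 25, 21), rnorm(25))
  expect_error(enumeratePosterior(big, priorSpec()), "m <= 20")
})
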