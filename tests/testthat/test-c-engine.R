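# Cross-implementation checks: the compiled state engine against the pure-R
# reference state and dense recomputation, and short chains against
# enumeration.

cDataset <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, 0.35), n, m)
  sp <- sort(sample.int(m, min(3L, m)))
  y <- rnorm(n, rowSums(X[, sp, drop = FALSE]) * 0.4)
  gwasData(X, y)
}

cStateNew <- function(gd, prior, tau2full, refactor = 1000L) {
  X <- gd@X; storage.mode(X) <- "double"
  cst <- .Call("C_state_new", X, as.numeric(gd@y),
               as.numeric(gd@columnSqNorms), prior@aPi, prior@bPi,
               prior@nuSigma, prior@s2Sigma, as.integer(gd@snpOrder),
               as.integer(refactor), PACKAGE = "SpikeSlabGWAS")
  .Call("C_state_set_tau2", cst, tau2full, PACKAGE = "SpikeSlabGWAS")
  cst
}

test_that("the C state replays an R-state walk bit-tight", {
  gd <- cDataset(40, 12, seed = 61)
  prior <- priorSpec()
  set.seed(62)
  tau2full <- runif(12, 0.05, 0.5)
  cst <- cStateNew(gd, prior, tau2full, refactor = 50L)
  rst <- SpikeSlabGWAS:::.stateNew(gd, prior)
  SpikeSlabGWAS:::.stateSetTau2(rst, tau2full)
  for (step in 1:300) {
    j <- sample.int(12, 1)
    if (rst$inModel[j]) {
      SpikeSlabGWAS:::.stateRemove(rst, j)
      .Call("C_state_remove", cst, as.integer(j), PACKAGE = "SpikeSlabGWAS")
    } else {
      okR <- SpikeSlabGWAS:::.stateAdd(rst, j, tau2full[j])
      okC <- .Call("C_state_add", cst, as.integer(j), tau2full[j],
                   PACKAGE = "SpikeSlabGWAS")
      expect_identical(okR, okC)
    }
    info <- .Call("C_state_info", cst, PACKAGE = "SpikeSlabGWAS")
    expect_identical(sort(info$incl), sort(rst$incl))
    expect_equal(info$logpost, rst$logpost, tolerance = 1e-9)
    dense <- logMarginalLikelihood(gd, prior, rst$incl,
                                   tau2full[rst$incl])
    expect_equal(info$logml, dense, tolerance = 1e-8)
    expect_equal(info$S, SpikeSlabGWAS:::.stateS(rst), tolerance = 1e-8)
  }
})

test_that("C_beta_draw matches the conditional mean and covariance scale", {
  gd <- cDataset(60, 6, seed = 63)
  prior <- priorSpec()
  tau2full <- rep(0.3, 6)
  cst <- cStateNew(gd, prior, tau2full)
  rst <- SpikeSlabGWAS:::.stateNew(gd, prior)
  SpikeSlabGWAS:::.stateSetTau2(rst, tau2full)
  for (j in c(1L, 3L, 5L)) {
    SpikeSlabGWAS:::.stateAdd(rst, j, tau2full[j])
    .Call("C_state_add", cst, j, tau2full[j], PACKAGE = "SpikeSlabGWAS")
  }
  set.seed(64)
  draws <- t(replicate(6000, .Call("C_beta_draw", cst, 0.7,
                                   PACKAGE = "SpikeSlabGWAS")))
  mu <- SpikeSlabGWAS:::.stateBetaMean(rst)
  expect_equal(colMeans(draws), mu, tolerance = 0.02)
  # covariance should be sigma2 * A^{-1}
  A <- crossprod(gd@X[, c(1, 3, 5)]) + diag(1 / tau2full[c(1, 3, 5)])
  expect_equal(cov(draws), 0.7 * solve(A), tolerance = 0.02)
})

test_that("each kernel's chain recovers the enumerated PIPs (fixed tau2)", {
  gd <- cDataset(40, 5, seed = 65)
  prior <- priorSpec(aPi = 1, bPi = 4)
  enum <- enumeratePosterior(gd, prior, tau2 = 0.3)
  for (sampler in c("ss", "ms", "msdr", "ksc", "nk")) {
    cfg <- runConfig(iterations = 30000L, thin = 2L, sampler = sampler,
                     fixedTau2 = 0.3, burninFraction = 0.2, seed = 66,
                     adaptive = sampler %in% c("ms", "msdr"),
                     adaptMoveSize = FALSE)
    tr <- runChain(gd, prior, cfg)
    keep <- (tr@burninKept + 1):nrow(tr@gammaTrace)
    pipEmp <- colMeans(tr@gammaTrace[keep, , drop = FALSE])
    expect_lt(max(abs(pipEmp - enum$pip)), 0.05,
              label = sprintf("empirical PIP error (%s)", sampler))
  }
})

test_that("every audited DR second-stage ratio is unity (small run)", {
  gd <- cDataset(30, 8, seed = 67)
  cfg <- runConfig(iterations = 4000L, thin = 4L, sampler = "msdr",
                   drAudit = TRUE, seed = 68)
  tr <- runChain(gd, priorSpec(), cfg)
  ratios <- tr@moveRecords$drRatio
  ratios <- ratios[!is.na(ratios)]
  expect_gt(length(ratios), 100)
  expect_lt(max(abs(ratios - 1)), 1e-8)
})

test_that("locus moves mix in and the chain stays correct", {
  gd <- cDataset(50, 12, seed = 69)
  cfg <- runConfig(iterations = 8000L, thin = 4L, sampler = "msdr",
                   kernelWeights = c(0.7, 0.15, 0.15), seed = 70,
                   drAudit = TRUE)
  tr <- runChain(gd, priorSpec(), cfg)
  kernels <- unique(tr@moveRecords$kernel)
  expect_true(all(c("msdr", "swap", "nbr") %in% kernels))
  ratios <- tr@moveRecords$drRatio
  ratios <- ratios[!is.na(ratios)]
  expect_lt(max(abs(ratios - 1)), 1e-8)
  # swap moves preserve model size by construction
  sw <- tr@moveRecords$kernel == "swap" & tr@moveRecords$accepted
  if (any(sw)) expect_true(all(tr@moveRecords$jump[sw] %% 2 == 0))
})
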