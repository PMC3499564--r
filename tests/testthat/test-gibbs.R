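# Orchestrator contracts: reproducibility, trace shape, the freeze, and
# the S4 surface.

gibbsData <- function(seed = 71) {
  set.seed(seed)
  X <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  y <- rnorm(60, X[, 2] * 0.5)
  gwasData(X, y)
}

test_that("runChain is a deterministic function of the seed", {
  gd <- gibbsData()
  cfg <- runConfig(iterations = 1500L, thin = 3L, sampler = "msdr",
                   kernelWeights = c(0.8, 0.1, 0.1), seed = 42)
  t1 <- runChain(gd, priorSpec(), cfg)
  t2 <- runChain(gd, priorSpec(), cfg)
  expect_identical(t1@gammaTrace, t2@gammaTrace)
  expect_identical(t1@logPost, t2@logPost)
  expect_identical(t1@sigma2, t2@sigma2)
  cfg@seed <- 43L
  t3 <- runChain(gd, priorSpec(), cfg)
  expect_false(identical(t1@gammaTrace, t3@gammaTrace))
})

test_that("runChain leaves the caller's RNG state untouched", {
  gd <- gibbsData()
  set.seed(99); before <- .Random.seed
  runChain(gd, priorSpec(), runConfig(iterations = 300L, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("the trace has coherent shapes and cached log-posteriors", {
  gd <- gibbsData()
  cfg <- runConfig(iterations = 2000L, thin = 5L, seed = 7)
  tr <- runChain(gd, priorSpec(), cfg)
  expect_s4_class(tr, "ChainTrace")
  expect_identical(dim(tr@gammaTrace), c(400L, 8L))
  expect_length(tr@modelSize, 400)
  expect_identical(nrow(tr@moveRecords), 2000L)
  expect_equal(tr@modelSize, rowSums(tr@gammaTrace))
  expect_identical(tr@burninKept, 200L)
  expect_true(all(tr@pipRB >= 0 & tr@pipRB <= 1))
  expect_true(all(tr@pve >= 0))
  expect_output(show(tr), "ChainTrace")
  expect_equal(pip(tr), tr@pipRB)
  expect_equal(pip(tr, "empirical"), tr@pipEmpirical)
  expect_identical(dim(keptGamma(tr)), dim(tr@gammaTrace[-(1:200), ]))
})

test_that("proposal parameters are frozen after burn-in", {
  gd <- gibbsData()
  cfg <- runConfig(iterations = 4000L, thin = 4L, sampler = "ms",
                   adaptive = TRUE, weightInterval = 200L,
                   moveSizeInterval = 500L, seed = 13)
  tr <- runChain(gd, priorSpec(), cfg)
  expect_identical(length(tr@psHash), 1L)
  expect_true(tr@pGeomFinal %in% seq(0.05, 0.95, by = 0.05) ||
                tr@pGeomFinal == 0.5)
})

test_that("fixedTau2 freezes the variance hierarchy", {
  gd <- gibbsData()
  cfg <- runConfig(iterations = 500L, fixedTau2 = 0.25, seed = 3)
  tr <- runChain(gd, priorSpec(), cfg)
  expect_true(all(is.na(tr@xi)))
  expect_true(all(is.finite(tr@sigma2)))
})

test_that("constructors validate their inputs", {
  expect_error(runConfig(iterations = 0), "iterations")
  expect_error(runConfig(kernelWeights = c(0.5, 0.5, 0.5)),
               "kernelWeights")
  expect_error(runConfig(sampler = "bogus"), "arg")
  expect_error(priorSpec(aPi = -1), "positive")
  expect_error(priorSpec(expectedAssociations = 5), "m is required")
  pr <- priorSpec(expectedAssociations = 10, m = 100)
  expect_equal(pr@bPi, 9)
  expect_error(gwasData(matrix(1, 3, 2), 1:2), "length")
  # missing dosages are mean-imputed, then centered
  X <- matrix(c(0, 1, 2, NA), 2, 2)
  gd <- gwasData(X, c(1, -1))
  expect_false(anyNA(gd@X))
  expect_equal(colMeans(gd@X), c(0, 0))
  expect_identical(nSamples(gd), 2L)
  expect_identical(nVariants(gd), 2L)
  expect_output(show(gd), "GwasData")
  expect_output(show(priorSpec()), "PriorSpec")
  expect_output(show(runConfig()), "RunConfig")
})

test_that("the sign-flip move is symmetric around muXi = 0", {
  pr <- priorSpec(muXi = 0, sigma2Xi = 1)
  set.seed(9)
  res <- SpikeSlabGWAS:::.signFlipMove(1.3, pr)
  expect_true(res$flip)           # logA = 0: always accepted
  expect_equal(res$xi, -1.3)
})
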