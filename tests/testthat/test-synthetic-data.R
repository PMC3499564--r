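# The synthetic GWAS generator and the adversarial pair fixture.

test_that("genotypes are valid dosages with LD block structure", {
  sp <- simSpec(n = 400, m = 40, ldBlockLength = 10, rho = 0.9,
                nCausal = 3)
  X <- simulateGenotypes(sp, seed = 7)
  expect_identical(dim(X), c(400L, 40L))
  expect_true(all(X %in% 0:2))
  expect_identical(storage.mode(X), "integer")
  expect_length(attr(X, "maf"), 40)
  # no monomorphic columns survive
  expect_true(all(apply(X, 2, function(col) length(unique(col)) > 1)))
  # deterministic in (spec, seed)
  expect_identical(X, simulateGenotypes(sp, seed = 7))
  expect_false(identical(X[, 1], simulateGenotypes(sp, seed = 8)[, 1]))
  # within-block adjacent correlation dominates cross-block correlation
  corAdj <- mean(vapply(c(1:8, 11:18, 21:28), function(j)
    abs(cor(X[, j], X[, j + 1])), numeric(1)))
  corFar <- mean(abs(cor(X[, 1:10], X[, 21:30])))
  expect_gt(corAdj, corFar + 0.2)
})

test_that("phenotype hits the target PVE exactly", {
  sp <- simSpec(n = 300, m = 30, nCausal = 4, pve = 0.35)
  X <- simulateGenotypes(sp, seed = 9)
  sim <- simulatePhenotype(X, sp, seed = 10)
  expect_length(sim$y, 300)
  expect_length(sim$truth$causal, 4)
  expect_equal(sim$truth$pveRealized, 0.35, tolerance = 1e-10)
  # recompute PVE from the returned truth
  signal <- as.vector(X[, sim$truth$causal] %*% sim$truth$effects)
  expect_equal(var(signal) / var(sim$y), 0.35, tolerance = 1e-10)
})

test_that("the pair trap asserts its marginal/joint contrast", {
  trap <- makePairTrap(n = 600, m = 20, seed = 3)
  j <- trap$truth$pair
  expect_identical(j, c(10L, 11L))
  expect_true(all(abs(trap$truth$tMarginal) < 2))
  expect_lt(trap$truth$pJoint, 1e-6)
  # the pair is tightly correlated and the effects cancel
  expect_gt(cor(trap$X[, j[1]], trap$X[, j[2]]), 0.8)
  expect_equal(sum(trap$truth$effects), 0)
  # re-verify the reported statistics from the data
  for (i in 1:2) {
    fit <- lm(trap$y ~ trap$X[, j[i]])
    expect_equal(summary(fit)$coefficients[2, 3], trap$truth$tMarginal[i],
                 tolerance = 1e-8)
  }
})

test_that("degenerate simulation requests error out", {
  expect_error(simSpec(n = 10, m = 5, nCausal = 6), "nCausal")
  expect_error(simSpec(rho = 1), "rho")
  sp <- simSpec(n = 50, m = 5, nCausal = 2, pve = 0.5)
  X <- simulateGenotypes(sp, 1)
  spBad <- simSpec(n = 50, m = 5, nCausal = 2, pve = 0.99)
  expect_silent(simulatePhenotype(X, spBad, 1))
  expect_error(makePairTrap(n = 50, m = 2, seed = 1), "m must be >= 3")
})
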