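# The multistep proposal machinery: size distribution, sequence sampling,
# exact log-probabilities (verified by exhaustive normalization), and the
# deterministic reverse.

test_that("truncGeomPmf normalizes and guards its domain", {
  expect_equal(sum(truncGeomPmf(1:20, 0.12, 20)), 1, tolerance = 1e-12)
  expect_equal(truncGeomPmf(1, 0.3, 1), 1)
  expect_equal(truncGeomPmf(c(0, 21, 1.5), 0.3, 20), c(0, 0, 0))
  expect_error(truncGeomPmf(1, 0, 20), "p must lie")
  expect_error(truncGeomPmf(1, 1, 20), "p must lie")
})

test_that("buildProposalWeights floors both sides", {
  w <- buildProposalWeights(c(0, 1, 0.3), epsMin = 0.05)
  expect_equal(w$add, c(0.05, 1, 0.3))
  expect_equal(w$remove, c(1, 0.05, 0.7))
  expect_error(buildProposalWeights(c(-0.1, 0.5), 0.05), "lie in")
  expect_error(buildProposalWeights(c(0.1, 0.5), 0), "positive")
})

# enumerate every realizable sequence from gamma and check the proposal
# probabilities sum to one (the tree including the size factor is a
# probability distribution over realized sequences)
enumerateSequences <- function(gamma, kMax) {
  m <- length(gamma)
  out <- list()
  recurse <- function(work, used, op, var) {
    canAdd <- which(!work & !used); canRem <- which(work & !used)
    len <- length(op)
    if (len > 0) out[[length(out) + 1L]] <<- list(op = op, var = var)
    if (len == kMax || (length(canAdd) == 0 && length(canRem) == 0)) return()
    for (j in canAdd) {
      w2 <- work; w2[j] <- TRUE; u2 <- used; u2[j] <- TRUE
      recurse(w2, u2, c(op, 1L), c(var, j))
    }
    for (j in canRem) {
      w2 <- work; w2[j] <- FALSE; u2 <- used; u2[j] <- TRUE
      recurse(w2, u2, c(op, -1L), c(var, j))
    }
  }
  recurse(gamma, logical(m), integer(0), integer(0))
  out
}

test_that("sequence probabilities sum to one over the full tree", {
  gamma <- c(FALSE, TRUE, TRUE, FALSE)
  kMax <- 3L
  seqs <- enumerateSequences(gamma, kMax)
  for (pGeom in c(0.3, 0.7)) {
    # uniform weights
    tot <- sum(vapply(seqs, function(z)
      exp(moveSequenceLogProb(gamma, z, pGeom = pGeom, kMax = kMax)),
      numeric(1)))
    # sequences of length < kMax that are NOT exhausted are only realized
    # when k equals their length; longer prefixes are separate outcomes --
    # the enumeration above lists every realizable sequence exactly once
    expect_equal(tot, 1, tolerance = 1e-10)
    # adapted (non-uniform) weights must still normalize
    psW <- list(addW = c(2, 0.5, 1, 3), removeW = c(1, 4, 0.25, 1),
                pGeom = pGeom, kMax = kMax)
    totW <- sum(vapply(seqs, function(z)
      exp(moveSequenceLogProb(gamma, z, psW)), numeric(1)))
    expect_equal(totW, 1, tolerance = 1e-10)
  }
})

test_that("full-tree normalization holds when exhaustion truncates", {
  # m = 2: every sequence exhausts at length 2 < kMax, exercising the
  # tail-probability size factor
  gamma <- c(TRUE, FALSE)
  seqs <- enumerateSequences(gamma, 5L)
  tot <- sum(vapply(seqs, function(z)
    exp(moveSequenceLogProb(gamma, z, pGeom = 0.4, kMax = 5L)),
    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("sampled sequences replay to their own log-probability", {
  set.seed(21)
  gamma <- c(rep(TRUE, 3), rep(FALSE, 5))
  ps <- list(addW = runif(8, 0.1, 1), removeW = runif(8, 0.1, 1),
             pGeom = 0.4, kMax = 6L)
  for (r in 1:50) {
    k <- sample.int(6, 1)
    z <- sampleMoveSequence(gamma, k, ps)
    expect_false(is.null(z))
    expect_false(anyDuplicated(z$var) > 0)
    sizeF <- if (z$exhausted)
      SpikeSlabGWAS:::.truncGeomLogTail(length(z$op), 0.4, 6L)
    else log(truncGeomPmf(length(z$op), 0.4, 6L))
    expect_equal(moveSequenceLogProb(gamma, z, ps),
                 z$logQSteps + sizeF, tolerance = 1e-12)
  }
})

test_that("reverse is an involution that undoes the move", {
  gamma <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  z <- list(op = c(1L, -1L, 1L), var = c(2L, 1L, 5L))
  gprime <- applyMoveSequence(gamma, z)
  expect_equal(gprime, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  zr <- reverseMoveSequence(z)
  expect_equal(applyMoveSequence(gprime, zr), gamma)
  expect_equal(reverseMoveSequence(zr), z)
})

test_that("illegal sequences are rejected", {
  gamma <- c(TRUE, FALSE)
  expect_error(applyMoveSequence(gamma, list(op = 1L, var = 1L)), "illegal")
  expect_error(applyMoveSequence(gamma, list(op = -1L, var = 2L)), "illegal")
  expect_identical(
    moveSequenceLogProb(gamma, list(op = c(1L, 1L), var = c(2L, 2L)),
                        pGeom = 0.5, kMax = 4L), -Inf)
  expect_identical(
    moveSequenceLogProb(gamma, list(op = 1L, var = 1L),
                        pGeom = 0.5, kMax = 4L), -Inf)
})
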