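# Metropolis-Hastings kernels over the inclusion indicators. All step
# functions mutate the internal model state environment in place and return
# a move record (list): kernel, kProposed, jump, accepted, accProb, drUsed,
# drRatio. The state carries tau2full (current slab variances for every
# variant) so additions know their tau_j^2.

.moveRecord <- function(kernel, kProposed = 0L, jump = 0L, accepted = FALSE,
                        accProb = 0, drUsed = FALSE, drRatio = NA_real_,
                        kDrawn = 0L) {
  list(kernel = kernel, kProposed = as.integer(kProposed),
       jump = as.integer(jump), accepted = accepted, accProb = accProb,
       drUsed = drUsed, drRatio = drRatio, kDrawn = as.integer(kDrawn))
}

# Apply an auxiliary sequence to the live state. Returns the number of
# successfully applied steps; a value < length(z$op) signals failure
# (saturation or a non-positive pivot) and the caller must revert.
.applySeqToState <- function(st, z) {
  nOk <- 0L
  for (s in seq_along(z$op)) {
    j <- z$var[s]
    ok <- if (z$op[s] == .OP_ADD) .stateAdd(st, j, st$tau2full[j]) else {
      .stateRemove(st, j); TRUE
    }
    if (!ok) return(nOk)
    nOk <- nOk + 1L
  }
  nOk
}

# Undo the first `upto` steps of z (applied in order) by applying their
# inverses in reverse order.
.revertSeqPrefix <- function(st, z, upto = length(z$op)) {
  for (s in rev(seq_len(upto))) {
    j <- z$var[s]
    if (z$op[s] == .OP_ADD) .stateRemove(st, j)
    else .stateAdd(st, j, st$tau2full[j])
  }
  invisible(st)
}

.sizeLogFactor <- function(len, exhausted, pGeom, kMax) {
  if (exhausted) .truncGeomLogTail(len, pGeom, kMax)
  else log(truncGeomPmf(len, pGeom, kMax))
}

# ---- main sequential-proposal step (SS / MS / MS-DR) ---------------------

.msLikeStep <- function(st, ps, cfg, singleStep = FALSE, dr = FALSE) {
  kernel <- if (singleStep) "ss" else if (dr) "msdr" else "ms"
  k <- if (singleStep || ps$kMax == 1L) 1L else .truncGeomSample(ps$pGeom, ps$kMax)
  rec <- .msLikeStepInner(st, ps, cfg, singleStep, dr, kernel, k)
  rec$kDrawn <- k
  rec
}

.msLikeStepInner <- function(st, ps, cfg, singleStep, dr, kernel, k) {
  gamma <- st$inModel
  z <- sampleMoveSequence(gamma, k, ps)
  if (is.null(z)) return(.moveRecord(kernel))
  len <- length(z$op)
  logqFwd <- z$logQSteps +
    if (singleStep) 0 else .sizeLogFactor(len, z$exhausted, ps$pGeom, ps$kMax)
  logpostOld <- st$logpost
  nOk <- .applySeqToState(st, z)
  if (nOk < len) {  # saturated or numerically refused: plain rejection
    .revertSeqPrefix(st, z, nOk)
    return(.moveRecord(kernel, kProposed = len))
  }
  gammaNew <- st$inModel
  zStar <- reverseMoveSequence(z)
  logqRev <- if (singleStep)
    .seqStepsLogProb(gammaNew, zStar, ps) else
    moveSequenceLogProb(gammaNew, zStar, ps)
  logA <- st$logpost + logqRev - logpostOld - logqFwd
  a <- if (logA >= 0) 1 else exp(logA)
  if (stats::runif(1) < a)
    return(.moveRecord(kernel, kProposed = len, jump = len, accepted = TRUE,
                       accProb = a))
  if (dr && len <= ps$drCutoff) {
    .drCacheOutside(st, ps, z$var)
    return(.drSecondStage(st, z, a, ps, cfg, kernel = kernel,
                          law = "weights"))
  }
  .revertSeqPrefix(st, z)
  .moveRecord(kernel, kProposed = len, accProb = a)
}

# step factors only (no size factor), for the single-step reverse
.seqStepsLogProb <- function(gamma, z, ps) {
  lq <- moveSequenceLogProb(gamma, z, ps)
  if (!is.finite(lq)) return(lq)
  # subtract the size factor the generic routine added
  work <- applyMoveSequence(gamma, z)
  used <- logical(length(gamma)); used[z$var] <- TRUE
  exhausted <- !any(!work & !used) && !any(work & !used)
  lq - .sizeLogFactor(length(z$op), exhausted, ps$pGeom, ps$kMax)
}

# ---- delayed rejection second stage --------------------------------------
#
# After a rejected first-stage move gamma -> gamma' through z (variables
# V in a realized order), the 2^k models reachable by flipping subsets of V
# are enumerated by a Gray-code walk of rank-one Cholesky updates. For each
# candidate m, its deterministic first-stage sequence z_m visits the same
# variables in the same order as z, with operation directions set by m's
# own inclusion states (so z_gamma is z itself, and the map is an
# involution); z_m ends at the complementary candidate m XOR V. The
# candidate is drawn proportional to
#     w(m) = post(m) * q(z_m | m) * (1 - a1(m -> m XOR V))
# and always accepted: the second-stage acceptance ratio cancels factor by
# factor, which drAudit verifies by independent dense recomputation.

.drSecondStage <- function(st, z, aFirst, ps, cfg, kernel, law) {
  kk <- length(z$op)
  vars <- z$var
  # saturation pre-check: the largest candidate must stay below n - 1
  # (rule depends only on the candidate set, keeping both routes symmetric)
  # reconstruct gamma's state of V: ops flipped each var once
  gammaState <- ifelse(z$op == .OP_ADD, FALSE, TRUE)
  qGamma <- st$q - sum(z$op == .OP_ADD) + sum(z$op == .OP_REMOVE)
  maxSize <- qGamma + sum(!gammaState)
  if (maxSize > st$n - 2L) {
    .revertSeqPrefix(st, z)
    return(.moveRecord(kernel, kProposed = kk, accProb = aFirst))
  }
  # walk back to gamma, then Gray-walk all subsets
  .revertSeqPrefix(st, z)
  nSub <- 2L^kk
  logpostTab <- numeric(nSub)
  logpostTab[1L] <- st$logpost
  curCode <- 0L
  bad <- FALSE
  for (t in seq_len(nSub - 1L)) {
    b <- 0L; tt <- t
    while (bitwAnd(tt, 1L) == 0L) { tt <- bitwShiftR(tt, 1L); b <- b + 1L }
    v <- vars[b + 1L]
    bit <- bitwShiftL(1L, b)
    flippedNow <- bitwAnd(curCode, bit) != 0L
    inGamma <- gammaState[b + 1L]
    nowIncluded <- xor(inGamma, flippedNow)
    ok <- if (nowIncluded) { .stateRemove(st, v); TRUE } else
      .stateAdd(st, v, st$tau2full[v])
    if (!ok) { bad <- TRUE; break }
    curCode <- bitwXor(curCode, bit)
    logpostTab[curCode + 1L] <- st$logpost
  }
  if (bad) {  # numerically refused pivot: walk home, plain rejection
    .drNavigate(st, curCode, 0L, vars, gammaState)
    return(.moveRecord(kernel, kProposed = kk, accProb = aFirst))
  }
  # per-candidate sequence log-probabilities under the move's own law
  lq <- .drSeqLogQ(st, ps, cfg, z, gammaState, law)      # forward, per code
  full <- nSub - 1L
  logw <- numeric(nSub)
  for (code in 0:full) {
    comp <- bitwXor(code, full)
    delta <- logpostTab[comp + 1L] + lq$rev[code + 1L] -
      logpostTab[code + 1L] - lq$fwd[code + 1L]
    logw[code + 1L] <- if (delta >= 0) -Inf else
      logpostTab[code + 1L] + lq$fwd[code + 1L] + log1p(-exp(delta))
  }
  if (all(!is.finite(logw))) {  # degenerate: remain at gamma
    .drNavigate(st, curCode, 0L, vars, gammaState)
    return(.moveRecord(kernel, kProposed = kk, accProb = aFirst,
                       drUsed = TRUE))
  }
  wts <- exp(logw - max(logw[is.finite(logw)]))
  pick <- .sampleProp(wts) - 1L
  .drNavigate(st, curCode, pick, vars, gammaState)
  jump <- sum(bitwAnd(pick, bitwShiftL(1L, 0:(kk - 1L))) != 0L)
  drRatio <- NA_real_
  if (isTRUE(cfg@drAudit))
    drRatio <- .drAuditRatio(st, ps, cfg, z, gammaState, vars, pick,
                             logw, law)
  .moveRecord(kernel, kProposed = kk, jump = jump, accepted = jump > 0L,
              accProb = aFirst, drUsed = TRUE, drRatio = drRatio)
}

# move the live state from subset code `from` to subset code `to`
.drNavigate <- function(st, from, to, vars, gammaState) {
  diffBits <- bitwXor(from, to)
  b <- 0L
  while (diffBits != 0L) {
    if (bitwAnd(diffBits, 1L) != 0L) {
      v <- vars[b + 1L]
      if (st$inModel[v]) .stateRemove(st, v)
      else if (!.stateAdd(st, v, st$tau2full[v]))
        stop("internal error: pivot refused while navigating candidates")
    }
    diffBits <- bitwShiftR(diffBits, 1L)
    b <- b + 1L
  }
  invisible(st)
}

# log q(z_m | m) and log q(reverse(z_m) | m XOR V) for every candidate
# subset code, under either the adaptive-weight law or the neighborhood
# uniform law.
.drSeqLogQ <- function(st, ps, cfg, z, gammaState, law) {
  kk <- length(z$op)
  nSub <- 2L^kk
  fwd <- numeric(nSub); rev_ <- numeric(nSub)
  if (law == "weights") {
    for (code in 0:(nSub - 1L)) {
      flip <- bitwAnd(code, bitwShiftL(1L, 0:(kk - 1L))) != 0L
      mState <- xor(gammaState, flip)
      fwd[code + 1L] <- .weightSeqLogQ(st, ps, z$var, mState, reversed = FALSE)
      rev_[code + 1L] <- .weightSeqLogQ(st, ps, z$var, !mState, reversed = TRUE)
    }
  } else {
    for (code in 0:(nSub - 1L)) {
      flip <- bitwAnd(code, bitwShiftL(1L, 0:(kk - 1L))) != 0L
      mState <- xor(gammaState, flip)
      fwd[code + 1L] <- .nbrSeqLogQCode(st, cfg, z$var, mState, reversed = FALSE)
      rev_[code + 1L] <- .nbrSeqLogQCode(st, cfg, z$var, !mState, reversed = TRUE)
    }
  }
  list(fwd = fwd, rev = rev_)
}

# Fast replay of a sequence over variable set V (given order) starting from
# a state that differs from the global state only on V. mState gives the
# start state of each V-variable (in z order); outside V the state equals
# gamma's. O(k) per call using precomputed outside-of-V weight sums.
.weightSeqLogQ <- function(st, ps, vars, mState, reversed) {
  kk <- length(vars)
  ord <- if (reversed) rev(seq_len(kk)) else seq_len(kk)
  # outside-of-V eligibility sums; st currently sits at SOME member of the
  # candidate class, which agrees with gamma outside V
  outAddSum <- st$outAddSum; outRemSum <- st$outRemSum
  outAddN <- st$outAddN; outRemN <- st$outRemN
  addW <- ps$addW; removeW <- ps$removeW
  stateV <- mState
  addSumV <- sum(addW[vars[!stateV]])
  remSumV <- sum(removeW[vars[stateV]])
  addNV <- sum(!stateV); remNV <- sum(stateV)
  logq <- 0
  for (i in ord) {
    v <- vars[i]
    doAdd <- !stateV[i]
    nAdd <- outAddN + addNV; nRem <- outRemN + remNV
    if (nAdd > 0L && nRem > 0L) logq <- logq + log(0.5)
    if (doAdd) {
      logq <- logq + log(addW[v]) - log(outAddSum + addSumV)
      addSumV <- addSumV - addW[v]; addNV <- addNV - 1L
    } else {
      logq <- logq + log(removeW[v]) - log(outRemSum + remSumV)
      remSumV <- remSumV - removeW[v]; remNV <- remNV - 1L
    }
    # v is used from here on; it no longer counts on either side
  }
  exhausted <- (outAddN + outRemN) == 0L
  logq + .sizeLogFactor(kk, exhausted, ps$pGeom, ps$kMax)
}

# Cache the outside-of-V sums on the state before a DR enumeration; they
# depend only on gamma outside V, which every candidate shares.
.drCacheOutside <- function(st, ps, vars) {
  m <- st$m
  outside <- rep(TRUE, m); outside[vars] <- FALSE
  incl <- st$inModel & outside
  excl <- !st$inModel & outside
  st$outAddSum <- sum(ps$addW[excl]); st$outAddN <- sum(excl)
  st$outRemSum <- sum(ps$removeW[incl]); st$outRemN <- sum(incl)
  invisible(st)
}

# independent recomputation of the second-stage acceptance ratio: all
# numerator factors evaluated densely (fresh factorizations, generic
# sequence replay), denominator factors taken from the sampler's caches
.drAuditRatio <- function(st, ps, cfg, z, gammaState, vars, pick, logw, law) {
  kk <- length(vars)
  full <- 2L^kk - 1L
  data <- st$auditData; prior <- st$auditPrior
  denseLogPost <- function(gammaVec) {
    incl <- which(gammaVec)
    if (length(incl) > st$n - 2L) return(-Inf)
    logMarginalLikelihood(data, prior, incl, st$tau2full[incl]) +
      logPriorGamma(length(incl), st$m, st$aPi, st$bPi)
  }
  gammaVec <- st$inModel   # currently at the drawn candidate; agrees with
  # gamma outside V, and codeVec overrides the V positions
  codeVec <- function(code) {
    flip <- bitwAnd(code, bitwShiftL(1L, 0:(kk - 1L))) != 0L
    g <- gammaVec
    g[vars] <- xor(gammaState, flip)
    g
  }
  seqFor <- function(code) {
    g <- codeVec(code)
    list(op = ifelse(g[vars], .OP_REMOVE, .OP_ADD), var = vars)
  }
  seqLogQDense <- function(code, reversed) {
    g <- codeVec(code)
    zz <- seqFor(code)
    if (reversed) { g <- codeVec(bitwXor(code, full)); zz <- reverseMoveSequence(zz) }
    if (law == "weights") moveSequenceLogProb(g, zz, ps)
    else .nbrSeqLogProbGeneric(st, cfg, g, zz)
  }
  densePart <- function(code) {
    lp <- denseLogPost(codeVec(code))
    lqF <- seqLogQDense(code, FALSE)
    lqR <- seqLogQDense(code, TRUE)
    lpC <- denseLogPost(codeVec(bitwXor(code, full)))
    delta <- lpC + lqR - lp - lqF
    if (delta >= 0) -Inf else lp + lqF + log1p(-exp(delta))
  }
  numer <- densePart(pick) + logw[1L]          # dense w(gamma'') * cached w(gamma)
  denom <- densePart(0L) + logw[pick + 1L]     # dense w(gamma)   * cached w(gamma'')
  exp(numer - denom)
}

# ---- comparison kernels ---------------------------------------------------

.kscStep <- function(st, cfg) {
  m <- st$m
  kk <- min(cfg@blockK, m)
  K <- sample.int(m, kk)
  inK <- st$inModel[K]
  qOut <- st$q - sum(inK)
  nSub <- 2L^kk
  bits <- bitwShiftL(1L, 0:(kk - 1L))
  sizes <- qOut + vapply(0:(nSub - 1L),
                         function(code) sum(bitwAnd(code, bits) != 0L), numeric(1))
  logPrior <- logPriorGamma(sizes, m, st$aPi, st$bPi)
  pr <- exp(logPrior - max(logPrior))
  pick <- .sampleProp(pr) - 1L
  newInK <- bitwAnd(pick, bits) != 0L
  flip <- which(newInK != inK)
  if (!length(flip)) return(.moveRecord("ksc", kProposed = 0L, jump = 0L,
                                        accepted = FALSE, accProb = 1))
  zz <- list(op = ifelse(inK[flip], .OP_REMOVE, .OP_ADD), var = K[flip])
  logpostOld <- st$logpost
  nOk <- .applySeqToState(st, zz)
  if (nOk < length(zz$op)) {
    .revertSeqPrefix(st, zz, nOk)
    return(.moveRecord("ksc", kProposed = length(flip)))
  }
  curCode <- sum(bits[inK])
  # forward and reverse proposal probabilities share the normalizer
  logA <- st$logpost + logPrior[curCode + 1L] -
    logpostOld - logPrior[pick + 1L]
  a <- if (logA >= 0) 1 else exp(logA)
  if (stats::runif(1) < a)
    return(.moveRecord("ksc", kProposed = length(flip), jump = length(flip),
                       accepted = TRUE, accProb = a))
  .revertSeqPrefix(st, zz)
  .moveRecord("ksc", kProposed = length(flip), accProb = a)
}

.nkStep <- function(st, cfg, pipHat, epsMin) {
  m <- st$m
  kk <- min(cfg@blockK, m)
  K <- sample.int(m, kk)
  p <- pmin(pmax(pipHat[K], epsMin), 1 - epsMin)
  inK <- st$inModel[K]
  newInK <- stats::runif(kk) < p
  logqFwd <- sum(log(ifelse(newInK, p, 1 - p)))
  logqRev <- sum(log(ifelse(inK, p, 1 - p)))
  flip <- which(newInK != inK)
  if (!length(flip)) return(.moveRecord("nk", kProposed = 0L, jump = 0L,
                                        accepted = FALSE, accProb = 1))
  zz <- list(op = ifelse(inK[flip], .OP_REMOVE, .OP_ADD), var = K[flip])
  logpostOld <- st$logpost
  nOk <- .applySeqToState(st, zz)
  if (nOk < length(zz$op)) {
    .revertSeqPrefix(st, zz, nOk)
    return(.moveRecord("nk", kProposed = length(flip)))
  }
  logA <- st$logpost + logqRev - logpostOld - logqFwd
  a <- if (logA >= 0) 1 else exp(logA)
  if (stats::runif(1) < a)
    return(.moveRecord("nk", kProposed = length(flip), jump = length(flip),
                       accepted = TRUE, accProb = a))
  .revertSeqPrefix(st, zz)
  .moveRecord("nk", kProposed = length(flip), accProb = a)
}

# ---- locus-neighborhood moves ---------------------------------------------
#
# Variants are ordered by snpOrder positions; the neighborhood of i is all
# variants within `neighborhoodCutoff` index positions.

.nbrWindow <- function(st, cfg, v) {
  pos <- st$orderPos[v]
  lo <- max(1L, pos - cfg@neighborhoodCutoff)
  hi <- min(st$m, pos + cfg@neighborhoodCutoff)
  w <- st$orderVar[lo:hi]
  w[w != v]
}

# swap move: an included variant trades places with an excluded neighbor;
# model size is preserved. Multiple swaps per proposal, count from a
# truncated geometric with the fixed parameter pSwap.
.swapStep <- function(st, cfg) {
  logpostOld <- st$logpost
  k <- .truncGeomSample(cfg@pSwap, cfg@kMax)
  used <- logical(st$m)
  pairsF <- list()
  logqFwd <- 0
  for (s in seq_len(k)) {
    step <- .swapPick(st, cfg, used)
    if (is.null(step)) break
    .stateRemove(st, step$i)
    ok <- .stateAdd(st, step$j, st$tau2full[step$j])
    if (!ok) { .stateAdd(st, step$i, st$tau2full[step$i]); break }
    logqFwd <- logqFwd + step$logp
    used[step$i] <- TRUE; used[step$j] <- TRUE
    pairsF[[length(pairsF) + 1L]] <- c(step$i, step$j)
  }
  len <- length(pairsF)
  if (len == 0L) return(.moveRecord("swap"))
  logqFwd <- logqFwd + .swapSizeFactor(st, cfg, used, len)
  revInfo <- .swapSeqLogProb(st, cfg, pairsF)
  logA <- st$logpost + revInfo - logpostOld - logqFwd
  a <- if (logA >= 0) 1 else exp(logA)
  if (stats::runif(1) < a)
    return(.moveRecord("swap", kProposed = 2L * len, jump = 2L * len,
                       accepted = TRUE, accProb = a))
  for (pr in rev(pairsF)) {  # undo swaps in reverse order
    .stateRemove(st, pr[2L])
    .stateAdd(st, pr[1L], st$tau2full[pr[1L]])
  }
  .moveRecord("swap", kProposed = 2L * len, accProb = a)
}

# one swap sub-move pick: uniform over included anchors that have at least
# one eligible excluded neighbor, then uniform over those neighbors
.swapPick <- function(st, cfg, used) {
  incl <- st$incl[!used[st$incl]]
  if (!length(incl)) return(NULL)
  nbrs <- lapply(incl, function(i) {
    w <- .nbrWindow(st, cfg, i)
    w[!st$inModel[w] & !used[w]]
  })
  ok <- lengths(nbrs) > 0L
  if (!any(ok)) return(NULL)
  iIdx <- which(ok)[if (sum(ok) == 1L) 1L else sample.int(sum(ok), 1L)]
  i <- incl[iIdx]
  cand <- nbrs[[iIdx]]
  j <- cand[if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)]
  list(i = i, j = j, logp = -log(sum(ok)) - log(length(cand)))
}

# size factor for a realized swap count (tail when no further swap is legal)
.swapSizeFactor <- function(st, cfg, used, len) {
  more <- !is.null(.swapPickProbe(st, cfg, used))
  .sizeLogFactor(len, !more, cfg@pSwap, cfg@kMax)
}

.swapPickProbe <- function(st, cfg, used) {
  incl <- st$incl[!used[st$incl]]
  for (i in incl) {
    w <- .nbrWindow(st, cfg, i)
    if (any(!st$inModel[w] & !used[w])) return(TRUE)
  }
  NULL
}

# reverse log-probability of a swap sequence: reversed order, pairs swapped;
# replayed on the live state (currently at gamma')
.swapSeqLogProb <- function(st, cfg, pairsF) {
  len <- length(pairsF)
  used <- logical(st$m)
  logq <- 0
  # replay on a virtual state: track inclusion flips locally
  inModel <- st$inModel
  for (t in rev(seq_len(len))) {
    i <- pairsF[[t]][2L]; j <- pairsF[[t]][1L]  # reverse swap: j' -> i'
    incl <- which(inModel & !used)
    okCount <- 0L; candCount <- 0L
    for (ii in incl) {
      w <- .nbrWindow(st, cfg, ii)
      nb <- w[!inModel[w] & !used[w]]
      if (length(nb)) {
        okCount <- okCount + 1L
        if (ii == i) candCount <- length(nb)
      }
    }
    if (okCount == 0L || candCount == 0L) return(-Inf)
    logq <- logq - log(okCount) - log(candCount)
    inModel[i] <- FALSE; inModel[j] <- TRUE
    used[i] <- TRUE; used[j] <- TRUE
  }
  # tail factor for the reverse direction
  incl <- which(inModel & !used)
  more <- FALSE
  for (ii in incl) {
    w <- .nbrWindow(st, cfg, ii)
    if (any(!inModel[w] & !used[w])) { more <- TRUE; break }
  }
  logq + .sizeLogFactor(len, !more, cfg@pSwap, cfg@kMax)
}

# ---- neighborhood toggle move --------------------------------------------
#
# Each sub-step draws a uniformly random eligible (anchor, neighbor) pair --
# anchor included, neighbor untouched and within the cutoff -- and toggles
# the neighbor. The per-step probability of toggling v marginalizes over
# anchors: partners(v) / #pairs. Delayed rejection over the toggled subset
# is available with the same always-accept construction as the main move.

.nbrPairs <- function(st, cfg, inModel, used) {
  incl <- which(inModel)
  if (!length(incl)) return(NULL)
  total <- 0L
  partner <- integer(0); pvar <- integer(0)
  for (i in incl) {
    w <- .nbrWindow(st, cfg, i)
    w <- w[!used[w]]
    if (length(w)) {
      total <- total + length(w)
      pvar <- c(pvar, w)
    }
  }
  if (total == 0L) return(NULL)
  list(total = total, pvar = pvar)
}

.nbrStep <- function(st, ps, cfg, dr = FALSE) {
  logpostOld <- st$logpost
  k <- .truncGeomSample(cfg@pNeighborhood, cfg@kMax)
  used <- logical(st$m)
  op <- integer(k); var <- integer(k)
  logqFwd <- 0
  len <- 0L
  for (s in seq_len(k)) {
    pairs <- .nbrPairs(st, cfg, st$inModel, used)
    if (is.null(pairs)) break
    v <- pairs$pvar[if (pairs$total == 1L) 1L else sample.int(pairs$total, 1L)]
    doAdd <- !st$inModel[v]
    ok <- if (doAdd) .stateAdd(st, v, st$tau2full[v]) else {
      .stateRemove(st, v); TRUE
    }
    if (!ok) break
    logqFwd <- logqFwd + log(sum(pairs$pvar == v)) - log(pairs$total)
    len <- len + 1L
    op[len] <- if (doAdd) .OP_ADD else .OP_REMOVE
    var[len] <- v
    used[v] <- TRUE
  }
  if (len == 0L) return(.moveRecord("nbr"))
  z <- list(op = op[seq_len(len)], var = var[seq_len(len)])
  more <- !is.null(.nbrPairs(st, cfg, st$inModel, used))
  logqFwd <- logqFwd + .sizeLogFactor(len, !more, cfg@pNeighborhood, cfg@kMax)
  zStar <- reverseMoveSequence(z)
  logqRev <- .nbrSeqLogProbGeneric(st, cfg, st$inModel, zStar)
  logA <- st$logpost + logqRev - logpostOld - logqFwd
  a <- if (logA >= 0) 1 else exp(logA)
  if (stats::runif(1) < a)
    return(.moveRecord("nbr", kProposed = len, jump = len, accepted = TRUE,
                       accProb = a))
  if (dr && len <= ps$drCutoff) {
    .drCacheOutside(st, ps, z$var)
    return(.drSecondStage(st, z, a, ps, cfg, kernel = "nbr", law = "nbr"))
  }
  .revertSeqPrefix(st, z)
  .moveRecord("nbr", kProposed = len, accProb = a)
}

# generic neighborhood-law sequence log-probability by full replay from an
# arbitrary inclusion vector (used for reverses and audits)
.nbrSeqLogProbGeneric <- function(st, cfg, gamma, z) {
  used <- logical(st$m)
  inModel <- gamma
  logq <- 0
  len <- length(z$op)
  for (s in seq_len(len)) {
    v <- z$var[s]
    if (used[v]) return(-Inf)
    doAdd <- z$op[s] == .OP_ADD
    if (doAdd == inModel[v]) return(-Inf)
    pairs <- .nbrPairs(st, cfg, inModel, used)
    if (is.null(pairs)) return(-Inf)
    cnt <- sum(pairs$pvar == v)
    if (cnt == 0L) return(-Inf)
    logq <- logq + log(cnt) - log(pairs$total)
    inModel[v] <- doAdd
    used[v] <- TRUE
  }
  more <- !is.null(.nbrPairs(st, cfg, inModel, used))
  logq + .sizeLogFactor(len, !more, cfg@pNeighborhood, cfg@kMax)
}

# neighborhood-law replay for a DR candidate given by its V-state vector
.nbrSeqLogQCode <- function(st, cfg, vars, mState, reversed) {
  kk <- length(vars)
  ord <- if (reversed) rev(seq_len(kk)) else seq_len(kk)
  gamma <- st$inModel
  gamma[vars] <- mState
  zz <- list(op = ifelse(if (reversed) rev(mState) else mState,
                         .OP_REMOVE, .OP_ADD),
             var = vars[ord])
  .nbrSeqLogProbGeneric(st, cfg, gamma, zz)
}

# Independent recomputation of a second-stage acceptance ratio from the
# engine's delayed-rejection detail record: every numerator factor is
# evaluated densely here (fresh factorizations, generic sequence replays),
# while the denominator factors come from the engine's cached weights, so a
# ratio of one certifies agreement between the two implementations.
# stMirror is a plain list mirroring the model state at the drawn
# candidate: m, n, tau2full, inModel, orderPos, orderVar.
.drAuditFromDetail <- function(data, prior, cfg, ps, stMirror, detail) {
  vars <- detail$vars
  gammaState <- detail$gammaState
  pick <- detail$pick
  kk <- length(vars)
  full <- 2L^kk - 1L
  law <- detail$law
  st <- stMirror
  denseLogPost <- function(gammaVec) {
    incl <- which(gammaVec)
    if (length(incl) > st$n - 2L) return(-Inf)
    logMarginalLikelihood(data, prior, incl, st$tau2full[incl]) +
      logPriorGamma(length(incl), st$m, prior@aPi, prior@bPi)
  }
  gammaVec <- st$inModel   # at the drawn candidate; agrees with gamma
  codeVec <- function(code) {  # outside V, V positions overridden
    flip <- bitwAnd(code, bitwShiftL(1L, 0:(kk - 1L))) != 0L
    g <- gammaVec
    g[vars] <- xor(gammaState, flip)
    g
  }
  seqFor <- function(code) {
    g <- codeVec(code)
    list(op = ifelse(g[vars], .OP_REMOVE, .OP_ADD), var = vars)
  }
  seqLogQDense <- function(code, reversed) {
    g <- codeVec(code)
    zz <- seqFor(code)
    if (reversed) { g <- codeVec(bitwXor(code, full)); zz <- reverseMoveSequence(zz) }
    if (law == "weights") moveSequenceLogProb(g, zz, ps)
    else .nbrSeqLogProbGeneric(st, cfg, g, zz)
  }
  densePart <- function(code) {
    lp <- denseLogPost(codeVec(code))
    lqF <- seqLogQDense(code, FALSE)
    lqR <- seqLogQDense(code, TRUE)
    lpC <- denseLogPost(codeVec(bitwXor(code, full)))
    delta <- lpC + lqR - lp - lqF
    if (delta >= 0) -Inf else lp + lqF + log1p(-exp(delta))
  }
  numer <- densePart(pick) + detail$logwGamma
  denom <- densePart(0L) + detail$logwPick
  exp(numer - denom)
}
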