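# Sequential multistep proposal machinery: move-size distribution, adaptive
# add/remove weight construction, auxiliary (operation, variant) sequences
# with their exact log proposal probabilities, and the deterministic reverse.
#
# A sequence is represented as a list with integer vectors $op (+1 add,
# -1 remove) and $var (variant indices), no variant appearing twice.

.OP_ADD <- 1L
.OP_REMOVE <- -1L

#' Truncated geometric move-size distribution
#'
#' pmf(k) proportional to p (1-p)^(k-1) on k = 1..kMax. The mode is always
#' at 1, a deliberately conservative choice for move sizes.
#'
#' @param k move size(s); values outside 1..kMax get probability 0.
#' @param p shape parameter in (0, 1).
#' @param kMax truncation point.
#' @return probabilities summing to 1 over 1..kMax.
#' @examples
#' sum(truncGeomPmf(1:20, 0.12, 20))
#' truncGeomPmf(1, 0.3, 1)
#' @export
truncGeomPmf <- function(k, p, kMax = 20L) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (kMax < 1L) stop("kMax must be >= 1")
  norm <- 1 - (1 - p)^kMax
  out <- ifelse(k >= 1 & k <= kMax & k == floor(k),
                p * (1 - p)^(k - 1) / norm, 0)
  as.numeric(out)
}

.truncGeomSample <- function(p, kMax) {
  u <- stats::runif(1) * (1 - (1 - p)^kMax)
  k <- 1L + as.integer(floor(log1p(-u) / log1p(-p)))
  min(k, kMax)  # guard the floating-point edge
}

# log P(size >= k) under the truncated geometric (used when a sequence
# exhausts all legal steps before reaching its drawn size)
.truncGeomLogTail <- function(k, p, kMax) {
  if (k <= 1L) return(0)
  if (k > kMax) return(-Inf)
  log((1 - p)^(k - 1) - (1 - p)^kMax) - log1p(-(1 - p)^kMax)
}

#' Adaptive add/remove weights from inclusion-probability estimates
#'
#' Addition weights are the estimated inclusion probabilities and removal
#' weights their complements, both floored at \code{epsMin} so every
#' variant keeps positive proposal probability (irreducibility).
#'
#' @param pipEstimates estimated inclusion probabilities in [0, 1].
#' @param epsMin positive floor (the samplers default to 1/m).
#' @return list with components \code{add} and \code{remove}.
#' @examples
#' buildProposalWeights(c(0.9, 0.1), epsMin = 0.01)
#' @export
buildProposalWeights <- function(pipEstimates, epsMin) {
  if (any(pipEstimates < 0 | pipEstimates > 1))
    stop("inclusion-probability estimates must lie in [0, 1]")
  if (epsMin <= 0) stop("epsMin must be positive")
  list(add = pmax(pipEstimates, epsMin),
       remove = pmax(1 - pipEstimates, epsMin))
}

# Proposal-state constructor (internal; mirrors the adaptive machinery's
# tunables). Uniform weights until adapted.
.proposalStateNew <- function(m, epsMin = 1 / m, pGeom = 0.5, kMax = 20L,
                              drCutoff = 10L) {
  ps <- new.env(parent = emptyenv())
  ps$addW <- rep(1, m)
  ps$removeW <- rep(1, m)
  ps$pGeom <- pGeom
  ps$kMax <- as.integer(kMax)
  ps$drCutoff <- as.integer(drCutoff)
  ps$epsMin <- epsMin
  ps$frozen <- FALSE
  ps
}

#' Sample a multistep auxiliary sequence
#'
#' Builds a sequence of up to \code{k} (operation, variant) steps from the
#' current indicator configuration: each step chooses addition or removal
#' with probability 0.5 (or the only possible direction), then draws the
#' variant from the renormalized adaptive weights over the still-eligible
#' variants; a variant used once is ineligible for the rest of the
#' sequence. The sequence is shorter than \code{k} only when no legal step
#' remains, in which case the returned log-probability accounts for the
#' realized length.
#'
#' @param gamma logical inclusion vector of length m.
#' @param k drawn move size (>= 1).
#' @param proposalState list with \code{add}/\code{remove} weight vectors
#'   (see \code{\link{buildProposalWeights}}); uniform if omitted.
#' @return \code{NULL} when no legal first step exists, else a list with
#'   \code{op} (+1/-1), \code{var}, \code{logQSteps} (log-probability of the
#'   realized direction/variant choices, excluding the move-size factor) and
#'   \code{exhausted} (TRUE when legality ran out before k steps).
#' @examples
#' set.seed(1)
#' gam <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
#' sampleMoveSequence(gam, 2L)
#' @export
sampleMoveSequence <- function(gamma, k, proposalState = NULL) {
  m <- length(gamma)
  if (is.null(proposalState)) {
    addW <- rep(1, m); removeW <- rep(1, m)
  } else {
    addW <- if (!is.null(proposalState$addW)) proposalState$addW else proposalState$add
    removeW <- if (!is.null(proposalState$removeW)) proposalState$removeW else proposalState$remove
  }
  work <- gamma
  used <- logical(m)
  op <- integer(k); var <- integer(k)
  logq <- 0
  len <- 0L
  for (s in seq_len(k)) {
    canAdd <- !work & !used
    canRemove <- work & !used
    nAdd <- sum(canAdd); nRemove <- sum(canRemove)
    if (nAdd == 0L && nRemove == 0L) break
    if (nAdd > 0L && nRemove > 0L) {
      doAdd <- stats::runif(1) < 0.5
      logq <- logq + log(0.5)
    } else doAdd <- nAdd > 0L
    if (doAdd) {
      cand <- which(canAdd); wts <- addW[cand]
    } else {
      cand <- which(canRemove); wts <- removeW[cand]
    }
    j <- cand[.sampleProp(wts)]
    logq <- logq + log(if (doAdd) addW[j] else removeW[j]) - log(sum(wts))
    len <- len + 1L
    op[len] <- if (doAdd) .OP_ADD else .OP_REMOVE
    var[len] <- j
    used[j] <- TRUE
    work[j] <- doAdd
  }
  if (len == 0L) return(NULL)
  # a sequence is "exhausted" when no legal continuation exists from its
  # final state; the size factor is then a tail probability (any drawn size
  # >= the realized length produces the same sequence)
  exhausted <- !any(!work & !used) && !any(work & !used)
  list(op = op[seq_len(len)], var = var[seq_len(len)], logQSteps = logq,
       exhausted = exhausted)
}

# weighted single draw, index into the weight vector
.sampleProp <- function(w) {
  cw <- cumsum(w)
  findInterval(stats::runif(1) * cw[length(w)], cw) + 1L
}

#' Apply an auxiliary sequence to an indicator configuration
#'
#' @param gamma logical inclusion vector.
#' @param z sequence as returned by \code{\link{sampleMoveSequence}}.
#' @return the updated logical vector; errors on an illegal operation
#'   (adding an included or removing an excluded variant).
#' @examples
#' gam <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
#' z <- list(op = c(1L, 1L), var = c(3L, 4L))
#' which(applyMoveSequence(gam, z))
#' @export
applyMoveSequence <- function(gamma, z) {
  for (s in seq_along(z$op)) {
    j <- z$var[s]
    if (z$op[s] == .OP_ADD) {
      if (gamma[j]) stop("illegal sequence: adding an included variant")
      gamma[j] <- TRUE
    } else {
      if (!gamma[j]) stop("illegal sequence: removing an excluded variant")
      gamma[j] <- FALSE
    }
  }
  gamma
}

#' Deterministic reverse of an auxiliary sequence
#'
#' Additions become removals and vice versa, with the step order reversed;
#' an involution, and applying the reverse to the proposed configuration
#' restores the original one.
#'
#' @param z an auxiliary sequence.
#' @return the reversed sequence.
#' @examples
#' z <- list(op = c(1L, 1L), var = c(3L, 4L))
#' reverseMoveSequence(z)  # remove 4, then remove 3
#' @export
reverseMoveSequence <- function(z) {
  list(op = rev(-z$op), var = rev(z$var))
}

#' Exact log proposal probability of a given sequence
#'
#' Replays \code{z} from \code{gamma} and accumulates the direction and
#' variant-choice factors plus the move-size factor of the truncated
#' geometric (a tail probability when the sequence exhausts every legal
#' step, since any larger drawn size realizes the same sequence).
#'
#' @param gamma logical inclusion vector the sequence starts from.
#' @param z auxiliary sequence.
#' @param proposalState environment/list with \code{addW}, \code{removeW},
#'   \code{pGeom}, \code{kMax} (as used by the samplers), or a list from
#'   \code{\link{buildProposalWeights}} plus \code{pGeom}/\code{kMax}
#'   arguments.
#' @param pGeom,kMax move-size distribution, read from
#'   \code{proposalState} when present there.
#' @return log q(z | gamma); \code{-Inf} for an illegal sequence.
#' @examples
#' gam <- rep(FALSE, 4)
#' z <- list(op = c(1L, 1L), var = c(2L, 3L))
#' moveSequenceLogProb(gam, z, pGeom = 0.5, kMax = 20L)
#' @export
moveSequenceLogProb <- function(gamma, z, proposalState = NULL,
                                pGeom = NULL, kMax = NULL) {
  m <- length(gamma)
  if (!is.null(proposalState)) {
    addW <- if (!is.null(proposalState$addW)) proposalState$addW else proposalState$add
    removeW <- if (!is.null(proposalState$removeW)) proposalState$removeW else proposalState$remove
    if (is.null(pGeom)) pGeom <- proposalState$pGeom
    if (is.null(kMax)) kMax <- proposalState$kMax
  } else {
    addW <- rep(1, m); removeW <- rep(1, m)
  }
  if (is.null(pGeom) || is.null(kMax))
    stop("pGeom and kMax are required (directly or via proposalState)")
  work <- gamma
  used <- logical(m)
  logq <- 0
  len <- length(z$op)
  for (s in seq_len(len)) {
    j <- z$var[s]
    if (used[j]) return(-Inf)
    doAdd <- z$op[s] == .OP_ADD
    if (doAdd && work[j]) return(-Inf)
    if (!doAdd && !work[j]) return(-Inf)
    canAdd <- !work & !used
    canRemove <- work & !used
    nAdd <- sum(canAdd); nRemove <- sum(canRemove)
    if (nAdd > 0L && nRemove > 0L) logq <- logq + log(0.5)
    if (doAdd) {
      logq <- logq + log(addW[j]) - log(sum(addW[canAdd]))
    } else {
      logq <- logq + log(removeW[j]) - log(sum(removeW[canRemove]))
    }
    used[j] <- TRUE
    work[j] <- doAdd
  }
  exhausted <- !any(!work & !used) && !any(work & !used)
  sizeFactor <- if (exhausted) .truncGeomLogTail(len, pGeom, kMax)
                else log(truncGeomPmf(len, pGeom, kMax))
  logq + sizeFactor
}
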