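# Model core: marginal log-likelihood of an indicator configuration with
# the coefficients and residual variance integrated out, the beta-binomial
# log prior on model size, and an incremental-Cholesky model state used by
# the samplers.
#
# With q included variants, D = diag(tau_j^2), A = X'X + D^{-1} = R'R
# (R upper triangular), w = R^{-T} X'y and S = y'y - w'w, the marginal is
#   log p(y | gamma, tau^2) = -1/2 sum log tau_j^2 - sum log diag(R)
#     + lgamma((nu+n-1)/2) - lgamma(nu/2) - ((n-1)/2) log(pi nu s2)
#     - ((nu+n-1)/2) log(1 + S/(nu s2))
# (n - 1 because centering absorbs one degree of freedom).

.mlConstant <- function(n, pr) {
  nu <- pr@nuSigma; s2 <- pr@s2Sigma
  lgamma((nu + n - 1) / 2) - lgamma(nu / 2) - ((n - 1) / 2) * log(pi * nu * s2)
}

#' Marginal log-likelihood of an indicator configuration
#'
#' Integrates the included effects and the residual variance out of the
#' centered linear model analytically (normal/scaled-inverse-chi-square
#' conjugacy), for fixed per-variant slab variances tau_j^2.
#'
#' @param data a \code{\linkS4class{GwasData}}.
#' @param prior a \code{\linkS4class{PriorSpec}}.
#' @param included integer indices of the included variants (may be empty).
#' @param tau2 slab variances for the included variants, recycled if scalar.
#' @return a finite scalar; depends only on the set of included indices.
#' @examples
#' gd <- gwasData(matrix(rnorm(60), 20, 3), rnorm(20))
#' pr <- priorSpec()
#' logMarginalLikelihood(gd, pr, integer(0))
#' logMarginalLikelihood(gd, pr, c(1L, 3L), tau2 = 0.5)
#' @export
logMarginalLikelihood <- function(data, prior, included, tau2 = 1) {
  included <- as.integer(included)
  q <- length(included)
  n <- nSamples(data)
  if (q > n - 2L) stop("saturated model: more than n - 2 included variants")
  tau2 <- rep_len(as.numeric(tau2), q)
  if (q && any(tau2 <= 0)) stop("invalid prior: tau2 must be positive")
  if (anyDuplicated(included)) stop("included indices must be distinct")
  yty <- sum(data@y^2)
  cst <- .mlConstant(n, prior)
  nu <- prior@nuSigma; s2 <- prior@s2Sigma
  if (q == 0L)
    return(cst - ((nu + n - 1) / 2) * log1p(yty / (nu * s2)))
  Xg <- data@X[, included, drop = FALSE]
  A <- crossprod(Xg)
  diag(A) <- diag(A) + 1 / tau2
  R <- chol(A)
  w <- backsolve(R, crossprod(Xg, data@y), transpose = TRUE)
  S <- yty - sum(w^2)
  -0.5 * sum(log(tau2)) - sum(log(diag(R))) + cst -
    ((nu + n - 1) / 2) * log1p(S / (nu * s2))
}

#' Beta-binomial log prior of an indicator configuration
#'
#' Log prior probability of a particular configuration with q of m
#' indicators set, after integrating the beta-distributed inclusion
#' probability analytically:
#' log B(aPi + q, bPi + m - q) - log B(aPi, bPi).
#'
#' @param q number of included variants.
#' @param m total number of variants.
#' @param aPi,bPi beta prior parameters.
#' @return scalar log prior of one configuration (not of the size class).
#' @examples
#' logPriorGamma(0, 5, 1, 1)
#' # ratio for growing the model by one:
#' logPriorGamma(3, 10, 1, 4) - logPriorGamma(2, 10, 1, 4)
#' @export
logPriorGamma <- function(q, m, aPi, bPi) {
  if (any(q < 0) || any(q > m)) stop("q must lie in [0, m]")
  lbeta(aPi + q, bPi + m - q) - lbeta(aPi, bPi)
}

#' Exact posterior by exhaustive enumeration
#'
#' Enumerates all 2^m indicator configurations at fixed slab variances,
#' evaluating each marginal likelihood by dense linear algebra (a fresh
#' factorization per model, no incremental caching), and returns normalized
#' posterior probabilities together with the exact per-variant inclusion
#' probabilities. Intended for desk-scale validation of the samplers.
#'
#' @param data a \code{\linkS4class{GwasData}} with at most ~15 variants.
#' @param prior a \code{\linkS4class{PriorSpec}}.
#' @param tau2 slab variances (recycled to m).
#' @return list with \code{models} (list of integer index vectors),
#'   \code{logPost} (unnormalized), \code{prob} (normalized),
#'   \code{pip} (length m), and \code{sizeProb} (model-size distribution).
#' @examples
#' gd <- gwasData(matrix(rnorm(80), 20, 4), rnorm(20))
#' enum <- enumeratePosterior(gd, priorSpec(), tau2 = 0.5)
#' sum(enum$prob)
#' @export
enumeratePosterior <- function(data, prior, tau2 = 1) {
  m <- nVariants(data)
  if (m > 20L) stop("enumeration is limited to m <= 20")
  tau2 <- rep_len(as.numeric(tau2), m)
  nModels <- 2L^m
  logPost <- numeric(nModels)
  models <- vector("list", nModels)
  sizes <- integer(nModels)
  for (code in 0:(nModels - 1L)) {
    incl <- which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    models[[code + 1L]] <- incl
    sizes[code + 1L] <- length(incl)
    ll <- if (length(incl) > nSamples(data) - 2L) -Inf else
      logMarginalLikelihood(data, prior, incl, tau2[incl])
    logPost[code + 1L] <- ll +
      logPriorGamma(length(incl), m, prior@aPi, prior@bPi)
  }
  pr <- exp(logPost - max(logPost))
  pr <- pr / sum(pr)
  pipExact <- numeric(m)
  for (i in seq_len(nModels)) {
    incl <- models[[i]]
    if (length(incl)) pipExact[incl] <- pipExact[incl] + pr[i]
  }
  sizeProb <- vapply(0:m, function(s) sum(pr[sizes == s]), numeric(1))
  names(sizeProb) <- 0:m
  list(models = models, logPost = logPost, prob = pr, pip = pipExact,
       sizeProb = sizeProb)
}

# ---- internal incremental model state ------------------------------------
#
# The state is an environment; samplers mutate it in place. Slots:
#   incl      integer, insertion-ordered included indices
#   inModel   logical(m)
#   q         model size
#   R         upper-triangular factor, active block [1:q, 1:q]
#   w         R^{-T} X_incl' y, active prefix 1:q
#   tau2      slab variances aligned with incl
#   logml, logprior, logpost   cached values
#   nMods     up/downdate counter since last full refactorization

.stateNew <- function(data, prior, capacity = 32L) {
  st <- new.env(parent = emptyenv())
  st$X <- data@X; st$y <- data@y
  st$n <- nrow(data@X); st$m <- ncol(data@X)
  st$yty <- sum(data@y^2)
  st$Xty <- as.numeric(crossprod(data@X, data@y))
  st$colSq <- data@columnSqNorms
  st$aPi <- prior@aPi; st$bPi <- prior@bPi
  st$nuSigma <- prior@nuSigma; st$s2Sigma <- prior@s2Sigma
  st$mlConst <- .mlConstant(st$n, prior)
  st$mlCoef <- (prior@nuSigma + st$n - 1) / 2
  capacity <- max(4L, min(capacity, st$n))
  st$R <- matrix(0, capacity, capacity)
  st$w <- numeric(capacity)
  st$tau2 <- numeric(capacity)
  st$incl <- integer(0)
  st$inModel <- logical(st$m)
  st$q <- 0L
  st$sumLogTau2 <- 0
  st$sumLogDiagR <- 0
  st$nMods <- 0L
  st$refactorInterval <- 1000L
  .stateRecache(st)
  st
}

.stateLogMl <- function(st) {
  S <- st$yty - sum(st$w[seq_len(st$q)]^2)
  -0.5 * st$sumLogTau2 - st$sumLogDiagR + st$mlConst -
    st$mlCoef * log1p(S / (st$nuSigma * st$s2Sigma))
}

.stateRecache <- function(st) {
  st$logml <- .stateLogMl(st)
  st$logprior <- logPriorGamma(st$q, st$m, st$aPi, st$bPi)
  st$logpost <- st$logml + st$logprior
  invisible(st)
}

# grow the preallocated factor storage
.stateGrow <- function(st) {
  cap <- nrow(st$R)
  newCap <- min(2L * cap, st$n)
  R2 <- matrix(0, newCap, newCap)
  R2[seq_len(cap), seq_len(cap)] <- st$R
  st$R <- R2
  length(st$w) <- newCap; st$w[is.na(st$w)] <- 0
  length(st$tau2) <- newCap; st$tau2[is.na(st$tau2)] <- 0
  invisible(st)
}

# Add variant j with slab variance tau2j; O(n q + q^2).
# Returns TRUE on success, FALSE when the pivot is numerically non-positive
# (the caller must treat the proposal as rejected).
.stateAdd <- function(st, j, tau2j) {
  q <- st$q
  if (st$inModel[j]) stop("variant already included")
  if (tau2j <= 0) stop("invalid prior: tau2 must be positive")
  if (q + 1L > st$n - 2L) return(FALSE)  # saturated-model guard
  if (q + 1L > nrow(st$R)) .stateGrow(st)
  if (q > 0L) {
    cvec <- as.numeric(crossprod(st$X[, st$incl, drop = FALSE], st$X[, j]))
    r12 <- backsolve(st$R, cvec, k = q, transpose = TRUE)
    d <- st$colSq[j] + 1 / tau2j - sum(r12^2)
  } else {
    r12 <- numeric(0)
    d <- st$colSq[j] + 1 / tau2j
  }
  if (d <= 1e-12 * (st$colSq[j] + 1 / tau2j)) {
    warning(sprintf("refusing to add variant %d: non-positive pivot", j))
    return(FALSE)
  }
  r22 <- sqrt(d)
  qn <- q + 1L
  if (q > 0L) st$R[seq_len(q), qn] <- r12
  st$R[qn, qn] <- r22
  st$w[qn] <- (st$Xty[j] - if (q > 0L) sum(r12 * st$w[seq_len(q)]) else 0) / r22
  st$tau2[qn] <- tau2j
  st$incl <- c(st$incl, as.integer(j))
  st$inModel[j] <- TRUE
  st$q <- qn
  st$sumLogTau2 <- st$sumLogTau2 + log(tau2j)
  st$sumLogDiagR <- st$sumLogDiagR + log(r22)
  st$nMods <- st$nMods + 1L
  if (st$nMods >= st$refactorInterval) .stateRefactor(st)
  .stateRecache(st)
  TRUE
}

# Remove included variant j; Givens-based column deletion, O(q^2).
.stateRemove <- function(st, j) {
  p <- match(as.integer(j), st$incl)
  if (is.na(p)) stop("variant not included")
  q <- st$q
  st$sumLogTau2 <- st$sumLogTau2 - log(st$tau2[p])
  if (p < q) {
    st$R[seq_len(q), p:(q - 1L)] <- st$R[seq_len(q), (p + 1L):q]
    st$tau2[p:(q - 1L)] <- st$tau2[(p + 1L):q]
    # rows p+1..q now intrude below the diagonal; rotate them away
    for (i in p:(q - 1L)) {
      a <- st$R[i, i]; b <- st$R[i + 1L, i]
      r <- sqrt(a * a + b * b)
      if (r > 0) {
        c0 <- a / r; s0 <- b / r
        cols <- i:(q - 1L)
        ri <- st$R[i, cols]; ri1 <- st$R[i + 1L, cols]
        st$R[i, cols] <- c0 * ri + s0 * ri1
        st$R[i + 1L, cols] <- -s0 * ri + c0 * ri1
        # the rotated diagonal entry is r > 0, so positivity is automatic
        wi <- st$w[i]; wi1 <- st$w[i + 1L]
        st$w[i] <- c0 * wi + s0 * wi1
        st$w[i + 1L] <- -s0 * wi + c0 * wi1
      }
    }
  }
  qn <- q - 1L
  st$R[seq_len(q), q] <- 0
  st$R[q, seq_len(q)] <- 0
  st$w[q] <- 0
  st$incl <- st$incl[-p]
  st$inModel[j] <- FALSE
  st$q <- qn
  st$sumLogDiagR <- if (qn > 0L) sum(log(diag(st$R)[seq_len(qn)])) else 0
  st$nMods <- st$nMods + 1L
  if (st$nMods >= st$refactorInterval) .stateRefactor(st)
  .stateRecache(st)
  invisible(st)
}

# Full refactorization, resetting accumulated floating-point drift.
.stateRefactor <- function(st) {
  q <- st$q
  st$nMods <- 0L
  if (q == 0L) {
    st$sumLogTau2 <- 0; st$sumLogDiagR <- 0
    return(invisible(st))
  }
  Xg <- st$X[, st$incl, drop = FALSE]
  A <- crossprod(Xg)
  diag(A) <- diag(A) + 1 / st$tau2[seq_len(q)]
  R <- chol(A)
  st$R[seq_len(q), seq_len(q)] <- R
  st$w[seq_len(q)] <- backsolve(R, st$Xty[st$incl], transpose = TRUE)
  st$sumLogTau2 <- sum(log(st$tau2[seq_len(q)]))
  st$sumLogDiagR <- sum(log(diag(R)))
  invisible(st)
}

# Rebuild the factorization after the slab variances changed (hyper sweep).
.stateSetTau2 <- function(st, tau2full) {
  if (st$q > 0L) st$tau2[seq_len(st$q)] <- tau2full[st$incl]
  .stateRefactor(st)
  .stateRecache(st)
  invisible(st)
}

# Posterior mean of the included coefficients (solve A mu = X'y).
.stateBetaMean <- function(st) {
  if (st$q == 0L) return(numeric(0))
  backsolve(st$R, st$w[seq_len(st$q)], k = st$q)
}

# Residual quadratic form S = y'y - w'w (used by the sigma^2 conditional).
.stateS <- function(st) st$yty - sum(st$w[seq_len(st$q)]^2)
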