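# Finite adaptation: Rao-Blackwellized inclusion-probability estimation
# feeding the proposal weights, and move-size parameter adaptation by
# expected jump distance with multiple importance sampling.

# ---- Rao-Blackwellized PIP estimator --------------------------------------

# running-mean estimator environment, warm-started at the prior mean with
# one pseudo-observation
.rbEstimatorNew <- function(m, aPi, bPi) {
  est <- new.env(parent = emptyenv())
  est$pipHat <- rep(aPi / (aPi + bPi), m)
  est$nUpdates <- 0L
  est
}

#' Rao-Blackwellized conditional inclusion probabilities
#'
#' For every variant j, regress the current residual (with variant j's own
#' contribution added back when it is included) on x_j alone and form the
#' closed-form Bayes factor for beta_j ~ N(0, sigma^2 tau_j^2) against
#' beta_j = 0; combined with the beta-binomial prior odds
#' (aPi + q_-j) / (bPi + m - 1 - q_-j) this yields the conditional
#' probability that gamma_j = 1 given the rest of the current state.
#'
#' @param data a \code{\linkS4class{GwasData}}.
#' @param prior a \code{\linkS4class{PriorSpec}}.
#' @param gamma logical inclusion vector.
#' @param beta current regression coefficients (length m, zero where
#'   excluded).
#' @param sigma2 current residual variance.
#' @param tau2 current effect-prior variances tau_j^2 (length m).
#' @return vector of conditional inclusion probabilities in [0, 1].
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- rnorm(20)
#' gd <- gwasData(X, y)
#' rbConditionalPip(gd, priorSpec(), rep(FALSE, 3), rep(0, 3), 1, rep(0.1, 3))
#' @export
rbConditionalPip <- function(data, prior, gamma, beta, sigma2, tau2) {
  X <- data@X
  m <- ncol(X)
  r <- data@y - as.vector(X %*% beta)
  xtr <- as.vector(crossprod(X, r))
  v <- data@columnSqNorms
  # add back j's own contribution for included variants: x_j'(r + x_j b_j)
  xtr <- xtr + beta * v
  logBF <- -0.5 * log1p(tau2 * v) +
    xtr^2 * tau2 / (2 * sigma2 * (1 + tau2 * v))
  qMinus <- sum(gamma) - as.numeric(gamma)
  logOdds <- logBF + log(prior@aPi + qMinus) -
    log(prior@bPi + m - 1 - qMinus)
  stats::plogis(logOdds)
}

# running-mean update of the estimator (mutates est in place)
.rbUpdate <- function(est, pCond) {
  n <- est$nUpdates + 1L
  # warm start counts as one observation at the prior mean
  est$pipHat <- est$pipHat + (pCond - est$pipHat) / (n + 1)
  est$nUpdates <- n
  invisible(est)
}

# ---- proposal-weight adaptation -------------------------------------------

# rebuild the add/remove weights from the current estimates; refuses to run
# after the finite-adaptation freeze
.adaptWeights <- function(ps, pipHat) {
  if (isTRUE(ps$frozen))
    stop("proposal adaptation attempted after the finite-adaptation freeze")
  w <- buildProposalWeights(pipHat, ps$epsMin)
  ps$addW <- w$add
  ps$removeW <- w$remove
  invisible(ps)
}

# ---- move-size adaptation by expected jump distance -----------------------

#' Expected-jump-distance objective for a candidate move-size parameter
#'
#' Estimates E[k a(k)] under the truncated geometric with parameter
#' \code{pCandidate} from history records collected under possibly several
#' parameter values, by multiple importance sampling with balance-heuristic
#' weights: w_i = pmf(k_i; pCandidate) / mean_s pmf(k_i; p_s) over the
#' distinct parameters present in the history. For indicator vectors the
#' squared jump distance equals the Hamming distance, so k times the
#' acceptance probability is the per-proposal expected squared jump.
#'
#' @param history data frame (or list) with numeric components \code{k}
#'   (proposed move sizes), \code{a} (acceptance probabilities) and
#'   \code{pUsed} (parameter in force when each move was proposed).
#' @param pCandidate candidate parameter in (0, 1).
#' @param kMax truncation point of the move-size distribution.
#' @return the self-normalized estimate of E[k a(k)] at \code{pCandidate}.
#' @examples
#' h <- list(k = c(1, 2, 1), a = c(1, 0.5, 1), pUsed = rep(0.5, 3))
#' ejdObjective(h, 0.3)
#' @export
ejdObjective <- function(history, pCandidate, kMax = 20L) {
  k <- history$k; a <- history$a; pUsed <- history$pUsed
  if (is.null(k) || length(k) == 0L) stop("history must be non-empty")
  if (length(a) != length(k) || length(pUsed) != length(k))
    stop("history components must have equal length")
  pLevels <- unique(pUsed)
  denom <- rowMeans(vapply(pLevels, function(p) truncGeomPmf(k, p, kMax),
                           numeric(length(k))))
  w <- truncGeomPmf(k, pCandidate, kMax) / denom
  sum(k * a * w) / sum(w)
}

#' Move-size parameter adaptation
#'
#' Returns the grid value maximizing \code{\link{ejdObjective}}.
#'
#' @inheritParams ejdObjective
#' @param grid candidate parameters in (0, 1).
#' @return the maximizing grid value.
#' @examples
#' h <- list(k = rep(1:3, 10), a = rep(1, 30), pUsed = rep(0.5, 30))
#' adaptMoveSize(h)  # acceptance 1 for all k: smallest p (longest moves)
#' @export
adaptMoveSize <- function(history, grid = seq(0.05, 0.95, by = 0.05),
                          kMax = 20L) {
  vals <- vapply(grid, function(p) ejdObjective(history, p, kMax), numeric(1))
  grid[which.max(vals)]
}
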