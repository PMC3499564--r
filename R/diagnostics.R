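# MCMC diagnostics: component-summed indicator autocovariance with the
# expected-jump identity, effective sample size by the initial monotone
# sequence estimator, the potential scale reduction factor, and the
# jump-distance move statistics.

#' Component-summed autocovariance of an indicator trace
#'
#' The lag-\code{lag} autocovariance of the indicator chain is defined as
#' the sum over variants of the per-variant autocovariances. At lag 0 this
#' is the summed variance V, and the mean squared jump distance per kept
#' step -- equal to the Hamming distance for binary vectors -- satisfies
#' E[jump^2] = 2 (V - cov_1).
#'
#' @param trace kept indicator samples, one row per kept iteration (a
#'   matrix of 0/1, e.g. \code{gammaTrace} of a
#'   \code{\linkS4class{ChainTrace}}).
#' @param lag nonnegative lag; needs at least \code{lag + 2} rows.
#' @return scalar; 0 for a constant trace.
#' @examples
#' g <- matrix(rbinom(200, 1, 0.5), 100, 2)
#' gammaAutocovariance(g, 0)  # summed variance, about 2 * 0.25
#' @export
gammaAutocovariance <- function(trace, lag = 1L) {
  trace <- as.matrix(trace)
  N <- nrow(trace)
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be nonnegative")
  if (N < lag + 2L) stop("need at least lag + 2 samples")
  mu <- colMeans(trace)
  a <- sweep(trace[seq_len(N - lag), , drop = FALSE], 2, mu)
  b <- sweep(trace[(1L + lag):N, , drop = FALSE], 2, mu)
  sum(colSums(a * b)) / (N - lag)
}

# biased autocovariance sequence via FFT (lags 0..N-1, denominator N)
.acovFFT <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  M <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(xc, rep(0, M - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / M
  ac[seq_len(n)] / n
}

#' Effective sample size by the initial monotone sequence estimator
#'
#' Forms paired autocorrelation sums Gamma_k = rho_{2k} + rho_{2k+1},
#' truncates at the first nonpositive pair, enforces monotone non-increase,
#' and sets act = 2 * sum(Gamma) - 1 (equivalently 1 + 2 sum rho), with
#' ess = N / act capped at N.
#'
#' @param x numeric series of length >= 10.
#' @return list with \code{act} (autocorrelation time, >= 1) and
#'   \code{ess}; a zero-variance series warns and reports \code{ess = N}.
#' @examples
#' set.seed(1)
#' geyerEss(rnorm(1000))$ess
#' @export
geyerEss <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 10L) stop("need at least 10 samples")
  if (stats::var(x) == 0) {
    warning("zero-variance series: ess defined as its length")
    return(list(act = 1, ess = N))
  }
  acov <- .acovFFT(x)
  rho <- acov / acov[1]
  nPair <- length(rho) %/% 2L
  Gam <- rho[2L * seq_len(nPair) - 1L] + rho[2L * seq_len(nPair)]
  K <- which(Gam <= 0)
  K <- if (length(K)) K[1] - 1L else nPair
  if (K == 0L) return(list(act = 1, ess = N))
  Gam <- cummin(Gam[seq_len(K)])
  act <- max(2 * sum(Gam) - 1, 1)
  list(act = act, ess = min(N / act, N))
}

#' Potential scale reduction factor
#'
#' The Gelman-Rubin statistic from two or more equal-length scalar chains:
#' sqrt of the ratio of the pooled variance estimate ((n-1)/n W + B/n) to
#' the mean within-chain variance W.
#'
#' @param chains list of two or more equal-length numeric vectors.
#' @return scalar >= 1 up to floating error; identical constant chains
#'   return 1 (degenerate sentinel).
#' @examples
#' set.seed(1)
#' psrf(list(rnorm(500), rnorm(500)))
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 2L) stop("chains must have length >= 2")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (W == 0) return(1)  # identical constant chains
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Jump-distance move statistics
#'
#' Arithmetic means of the per-iteration move records: realized jump
#' distance (RJD, mean number of indicator changes per iteration), proposed
#' jump distance (PJD), their ratio, and the move rate (fraction of
#' iterations with at least one change).
#'
#' @param moveRecords data frame with columns \code{jump} and
#'   \code{kProposed} (e.g. \code{moveRecords} of a
#'   \code{\linkS4class{ChainTrace}}).
#' @return list with \code{rjd}, \code{pjd}, \code{rjdOverPjd} and
#'   \code{moveRate}.
#' @examples
#' mr <- data.frame(jump = c(0L, 2L, 1L), kProposed = c(1L, 2L, 1L))
#' moveStatistics(mr)
#' @export
moveStatistics <- function(moveRecords) {
  if (nrow(moveRecords) == 0L) stop("move records must be non-empty")
  rjd <- mean(moveRecords$jump)
  pjd <- mean(moveRecords$kProposed)
  list(rjd = rjd, pjd = pjd,
       rjdOverPjd = if (pjd > 0) rjd / pjd else NA_real_,
       moveRate = mean(moveRecords$jump > 0))
}

#' Efficiency report for a finished chain
#'
#' Combines the jump-distance move statistics with effective sample sizes of the
#' model-size trace and of the per-step Hamming displacement series (the
#' two candidate scalarizations of indicator-chain efficiency), each with
#' an efficiency per second of indicator-update time.
#'
#' @param trace a \code{\linkS4class{ChainTrace}}.
#' @param discardBurnin drop kept samples inside burn-in before computing
#'   effective sample sizes.
#' @return list with the move statistics plus \code{essModelSize},
#'   \code{essHamming}, \code{essModelSizePerSecond},
#'   \code{essHammingPerSecond}, \code{pGeomFinal} and
#'   \code{step3Seconds}.
#' @examples
#' set.seed(4)
#' gd <- gwasData(matrix(rbinom(400, 2, 0.3), 100, 4), rnorm(100))
#' tr <- runChain(gd, priorSpec(), runConfig(iterations = 500, seed = 1))
#' chainEfficiency(tr)$essModelSize
#' @export
chainEfficiency <- function(trace, discardBurnin = TRUE) {
  keep <- if (discardBurnin && trace@burninKept > 0L)
    (trace@burninKept + 1L):length(trace@modelSize)
  else seq_along(trace@modelSize)
  ms <- trace@modelSize[keep]
  gam <- trace@gammaTrace[keep, , drop = FALSE]
  ham <- rowSums(abs(diff(gam)))
  essMs <- geyerEss(ms)$ess
  essHam <- if (stats::var(ham) == 0) length(ham) else geyerEss(ham)$ess
  stats <- moveStatistics(trace@moveRecords)
  tSec <- trace@step3Seconds
  c(stats,
    list(essModelSize = essMs, essHamming = essHam,
         essModelSizePerSecond = if (tSec > 0) essMs / tSec else NA_real_,
         essHammingPerSecond = if (tSec > 0) essHam / tSec else NA_real_,
         pGeomFinal = trace@pGeomFinal, step3Seconds = tSec))
}

#' Goodness of fit of sampled models against an enumerated posterior
#'
#' Chi-square goodness-of-fit test of the visited-model distribution
#' against exact enumeration probabilities. Correlated MCMC draws violate
#' the test's independence assumption, so the counts are rescaled to an
#' effective sample size before forming the statistic; cells with tiny
#' expected counts are pooled.
#'
#' @param codes integer model codes of the kept samples (0..2^m-1, bit j
#'   set when variant j is included).
#' @param prob enumerated probabilities indexed by code + 1.
#' @param ess effective number of independent samples (defaults to the
#'   number of draws, i.e. the plain chi-square test).
#' @param minExpected pool cells with expected count below this value.
#' @return list with \code{statistic}, \code{df} and \code{pValue}.
#' @examples
#' set.seed(1)
#' p <- c(0.4, 0.3, 0.2, 0.1)
#' draws <- sample(0:3, 5000, TRUE, p)
#' modelGof(draws, p)$pValue > 0.01
#' @export
modelGof <- function(codes, prob, ess = length(codes), minExpected = 5) {
  nCells <- length(prob)
  counts <- tabulate(codes + 1L, nbins = nCells)
  scale <- ess / sum(counts)
  counts <- counts * scale
  expected <- prob * ess
  ord <- order(expected, decreasing = TRUE)
  counts <- counts[ord]; expected <- expected[ord]
  keep <- expected >= minExpected
  if (!all(keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    expected <- c(expected[keep], sum(expected[!keep]))
  }
  pos <- expected > 0
  stat <- sum((counts[pos] - expected[pos])^2 / expected[pos])
  df <- max(sum(pos) - 1L, 1L)
  list(statistic = stat, df = df,
       pValue = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Encode kept indicator samples as integer model codes
#'
#' @param gammaTrace 0/1 matrix, one row per kept sample (m <= 25).
#' @return integer vector of codes (bit j set when variant j is included).
#' @examples
#' gammaCodes(rbind(c(1, 0), c(1, 1)))
#' @export
gammaCodes <- function(gammaTrace) {
  m <- ncol(gammaTrace)
  if (m > 25L) stop("model codes are limited to m <= 25")
  as.integer(gammaTrace %*% 2L^(seq_len(m) - 1L))
}
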