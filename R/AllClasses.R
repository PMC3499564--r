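#' @import methods
NULL

#' Centered genotype/phenotype container
#'
#' Holds an n x m genotype dosage matrix and a length-n continuous phenotype,
#' both stored centered so that the regression intercept is integrated out
#' exactly under a flat prior. Column means and squared norms are cached for
#' fast marginal-likelihood evaluation; \code{snpOrder} fixes the linear
#' genomic ordering used by the locus-neighborhood moves.
#'
#' @slot X centered dosage matrix (n individuals x m variants).
#' @slot y centered phenotype vector (length n).
#' @slot columnMeans per-variant dosage means before centering.
#' @slot columnSqNorms per-variant squared column norms of the centered X.
#' @slot snpOrder integer ranks giving the genomic order of the m variants.
#' @slot variantIds character variant identifiers.
#'
#' @export
setClass("GwasData", representation(
  X = "matrix",
  y = "numeric",
  columnMeans = "numeric",
  columnSqNorms = "numeric",
  snpOrder = "integer",
  variantIds = "character"
))

setValidity("GwasData", function(object) {
  n <- nrow(object@X); m <- ncol(object@X)
  msg <- character()
  if (n < 2L || m < 1L) msg <- c(msg, "need n >= 2 individuals and m >= 1 variants")
  if (length(object@y) != n) msg <- c(msg, "length(y) must equal nrow(X)")
  if (anyNA(object@X) || anyNA(object@y)) msg <- c(msg, "X and y must be free of missing values after imputation")
  if (length(object@columnMeans) != m) msg <- c(msg, "columnMeans length mismatch")
  if (length(object@columnSqNorms) != m) msg <- c(msg, "columnSqNorms length mismatch")
  if (length(object@snpOrder) != m) msg <- c(msg, "snpOrder length mismatch")
  if (m > 0 && max(abs(colMeans(object@X))) > 1e-6 * (1 + max(abs(object@X))))
    msg <- c(msg, "X must be stored centered")
  if (abs(mean(object@y)) > 1e-6 * (1 + max(abs(object@y))))
    msg <- c(msg, "y must be stored centered")
  if (length(msg)) msg else TRUE
})

#' Prior hyperparameters of the sparse linear model
#'
#' Fixed hyperparameters of the hierarchical prior: a scaled-inverse-chi^2
#' prior on the residual variance sigma^2 (\code{nuSigma}, \code{s2Sigma}),
#' scaled-inverse-chi^2 priors on the per-variant variance components s_j^2
#' (\code{nuS}, \code{s2S}), a normal prior on the expansion scalar xi
#' (\code{muXi}, \code{sigma2Xi}) and a beta prior on the inclusion
#' probability (\code{aPi}, \code{bPi}).  The effect-size prior is the
#' parameter-expanded form beta_j = xi * b_j with
#' b_j | gamma_j = 1 ~ N(0, sigma^2 s_j^2), so the marginal slab variance is
#' sigma^2 tau_j^2 with tau_j^2 = xi^2 s_j^2, a noncentral-F-type
#' distribution when xi has nonzero prior mean.
#'
#' @slot nuSigma,s2Sigma residual-variance prior degrees of freedom and scale.
#' @slot nuS,s2S variance-component prior degrees of freedom and scale.
#' @slot muXi,sigma2Xi mean and variance of the normal prior on xi.
#' @slot aPi,bPi beta prior parameters of the inclusion probability.
#'
#' @export
setClass("PriorSpec", representation(
  nuSigma = "numeric", s2Sigma = "numeric",
  nuS = "numeric", s2S = "numeric",
  muXi = "numeric", sigma2Xi = "numeric",
  aPi = "numeric", bPi = "numeric"
))

setValidity("PriorSpec", function(object) {
  vals <- c(object@nuSigma, object@s2Sigma, object@nuS, object@s2S,
            object@sigma2Xi, object@aPi, object@bPi)
  if (length(vals) != 7L || anyNA(vals) || any(vals <= 0))
    return("all degrees of freedom, scales, sigma2Xi, aPi and bPi must be positive")
  if (length(object@muXi) != 1L || !is.finite(object@muXi))
    return("muXi must be a finite scalar")
  TRUE
})

#' Sampler run configuration
#'
#' All tunables of \code{\link{runChain}}: chain length, thinning, burn-in
#' fraction, hyperparameter update interval, the indicator-update kernel and
#' its mixing weights with the two locus-neighborhood moves, adaptation
#' schedule and the proposal-distribution constants.
#'
#' @slot iterations total number of indicator-update iterations.
#' @slot thin keep every \code{thin}-th sample.
#' @slot burninFraction fraction of iterations discarded (and used for
#'   adaptation) at the start of the chain.
#' @slot hyperUpdateInterval hyperparameter Gibbs sweep interval (the
#'   comparison kernels conventionally use 100, the rest 10).
#' @slot sampler one of \code{"ss"}, \code{"ms"}, \code{"msdr"},
#'   \code{"ksc"}, \code{"nk"}.
#' @slot blockK block size of the comparison kernels.
#' @slot kernelWeights mixing probabilities of (main update, swap move,
#'   neighborhood toggle move).
#' @slot kMax move-size truncation point of the truncated geometric.
#' @slot drCutoff largest first-stage move size eligible for delayed
#'   rejection.
#' @slot epsMin relative floor of the adaptive add/remove weights.
#' @slot pGeomInit initial truncated-geometric move-size parameter.
#' @slot adaptive adapt add/remove weights from Rao-Blackwellized inclusion
#'   probabilities during burn-in.
#' @slot adaptMoveSize adapt the move-size parameter by expected jump
#'   distance (allowed also for non-adaptive multistep samplers).
#' @slot rbInterval,weightInterval,moveSizeInterval adaptation schedule.
#' @slot neighborhoodCutoff index-distance cutoff of the locus moves.
#' @slot pSwap,pNeighborhood fixed geometric parameters of the locus moves.
#' @slot fixedTau2 fixed effect-prior variances tau_j^2; when non-empty the
#'   (s^2, xi) hierarchy is frozen so the indicator chain targets an
#'   enumerable posterior.
#' @slot drAudit record an independently recomputed second-stage acceptance
#'   ratio for every delayed-rejection event.
#' @slot refactorInterval full Cholesky refactorization interval (in
#'   up/downdates) resetting floating-point drift.
#' @slot seed master RNG seed.
#'
#' @export
setClass("RunConfig", representation(
  iterations = "integer", thin = "integer", burninFraction = "numeric",
  hyperUpdateInterval = "integer", sampler = "character", blockK = "integer",
  kernelWeights = "numeric", kMax = "integer", drCutoff = "integer",
  epsMin = "numeric", pGeomInit = "numeric",
  adaptive = "logical", adaptMoveSize = "logical",
  rbInterval = "integer", weightInterval = "integer",
  moveSizeInterval = "integer",
  neighborhoodCutoff = "integer", pSwap = "numeric", pNeighborhood = "numeric",
  fixedTau2 = "numeric", drAudit = "logical",
  refactorInterval = "integer", seed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@burninFraction < 0 || object@burninFraction >= 1)
    msg <- c(msg, "burninFraction must be in [0, 1)")
  if (object@hyperUpdateInterval < 1L) msg <- c(msg, "hyperUpdateInterval must be >= 1")
  if (!object@sampler %in% c("ss", "ms", "msdr", "ksc", "nk"))
    msg <- c(msg, "sampler must be one of ss, ms, msdr, ksc, nk")
  if (length(object@kernelWeights) != 3L || any(object@kernelWeights < 0) ||
      abs(sum(object@kernelWeights) - 1) > 1e-8)
    msg <- c(msg, "kernelWeights must be 3 nonnegative values summing to 1")
  if (object@kMax < 1L) msg <- c(msg, "kMax must be >= 1")
  if (object@pGeomInit <= 0 || object@pGeomInit >= 1)
    msg <- c(msg, "pGeomInit must be in (0, 1)")
  if (!is.na(object@epsMin) && object@epsMin <= 0)
    msg <- c(msg, "epsMin must be > 0")  # NA means "resolve to 1/m at run time"
  if (length(msg)) msg else TRUE
})

#' Thinned MCMC output and per-iteration move records
#'
#' @slot gammaTrace kept indicator samples (kept iterations x m, 0/1).
#' @slot modelSize,sigma2,xi,pve,logPost kept scalar traces.
#' @slot moveRecords per-iteration move bookkeeping (proposed size, realized
#'   jump, acceptance probability, kernel id, delayed-rejection flag and
#'   audited second-stage ratio).
#' @slot pipRB final Rao-Blackwellized inclusion-probability estimates.
#' @slot pipEmpirical empirical inclusion probabilities over kept samples.
#' @slot pGeomFinal move-size parameter in force after freezing.
#' @slot psHash distinct fingerprints of the proposal parameters observed
#'   after the finite-adaptation freeze (length 1 certifies a fixed kernel).
#' @slot step3Seconds wall time spent in the indicator-update step only.
#' @slot burninKept number of kept samples that fall inside burn-in.
#' @slot config the \code{RunConfig} that produced the trace.
#'
#' @export
setClass("ChainTrace", representation(
  gammaTrace = "matrix", modelSize = "numeric", sigma2 = "numeric",
  xi = "numeric", pve = "numeric", logPost = "numeric",
  moveRecords = "data.frame", pipRB = "numeric", pipEmpirical = "numeric",
  pGeomFinal = "numeric", psHash = "character", step3Seconds = "numeric",
  burninKept = "integer", config = "RunConfig"
))

#' Simulation design of the synthetic GWAS generator
#'
#' Describes a study with \code{n} individuals and \code{m} variants laid
#' out in linkage-disequilibrium blocks (latent Gaussian AR(rho) haplotypes
#' thresholded at per-variant minor-allele frequencies under Hardy-Weinberg
#' pairing), \code{nCausal} causal variants with double-exponential effect
#' sizes, and Gaussian noise scaled so the realized proportion of variance
#' explained equals \code{pve} exactly.
#'
#' @slot n,m individuals and variants.
#' @slot ldBlockLength variants per LD block.
#' @slot rho latent within-block AR(1) correlation, in [0, 1).
#' @slot mafRange minor-allele frequency range, within (0, 0.5].
#' @slot nCausal number of causal variants.
#' @slot effectScale scale of the double-exponential effect distribution.
#' @slot pve target proportion of variance explained, in (0, 1).
#'
#' @export
setClass("SimSpec", representation(
  n = "integer", m = "integer", ldBlockLength = "integer", rho = "numeric",
  mafRange = "numeric", nCausal = "integer", effectScale = "numeric",
  pve = "numeric"
))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an increasing pair within (0, 0.5]")
  if (object@nCausal > object@m) msg <- c(msg, "nCausal must be <= m")
  if (object@pve <= 0 || object@pve >= 1) msg <- c(msg, "pve must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
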