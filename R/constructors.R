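#' Build a GwasData object from raw dosages and phenotype
#'
#' Mean-imputes missing dosages, then centers both the genotype columns and
#' the phenotype so the intercept is integrated out exactly. Dosage columns
#' are not variance-standardized: effect sizes stay on the per-allele scale.
#'
#' @param X numeric n x m dosage matrix (values in [0, 2]; NA allowed).
#' @param y numeric phenotype vector of length n (NA not allowed).
#' @param snpOrder optional integer genomic order of the variants; defaults
#'   to column order.
#' @param variantIds optional variant identifiers.
#' @return a \code{\linkS4class{GwasData}} object.
#' @examples
#' X <- matrix(rbinom(40, 2, 0.3), 10, 4)
#' y <- rnorm(10)
#' gd <- gwasData(X, y)
#' nVariants(gd)
#' @export
gwasData <- function(X, y, snpOrder = seq_len(ncol(X)), variantIds = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype must not contain missing values")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(cm)) stop("genotype columns with all values missing are not allowed")
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2L]]
  }
  Xc <- sweep(X, 2L, colMeans(X), "-")
  yc <- y - mean(y)
  if (is.null(variantIds)) {
    variantIds <- colnames(X)
    if (is.null(variantIds)) variantIds <- sprintf("snp%d", seq_len(ncol(X)))
  }
  new("GwasData",
      X = Xc, y = yc, columnMeans = cm,
      columnSqNorms = colSums(Xc^2),
      snpOrder = as.integer(snpOrder), variantIds = as.character(variantIds))
}

#' @describeIn gwasData number of individuals.
#' @param object,x a \code{GwasData} object.
#' @export
nSamples <- function(object) nrow(object@X)

#' @describeIn gwasData number of variants.
#' @export
nVariants <- function(object) ncol(object@X)

#' @describeIn gwasData centered genotype matrix.
#' @export
genotypes <- function(object) object@X

#' @describeIn gwasData centered phenotype vector.
#' @export
phenotype <- function(object) object@y

setMethod("show", "GwasData", function(object) {
  cat(sprintf("GwasData: %d individuals x %d variants (centered dosages)\n",
              nSamples(object), nVariants(object)))
})

#' Construct a PriorSpec
#'
#' The inclusion prior may be given either as \code{aPi}/\code{bPi} or
#' through the expected number of associations E, with
#' E = m * aPi / (aPi + bPi); in the latter case \code{aPi} is kept and
#' \code{bPi} solved for.
#'
#' @param nuSigma,s2Sigma residual-variance prior.
#' @param nuS,s2S variance-component prior.
#' @param muXi,sigma2Xi expansion-scalar prior.
#' @param aPi,bPi inclusion-probability beta prior.
#' @param expectedAssociations optional expected model size E.
#' @param m number of variants (required with \code{expectedAssociations}).
#' @return a \code{\linkS4class{PriorSpec}} object.
#' @examples
#' priorSpec(expectedAssociations = 5, m = 1000)
#' @export
priorSpec <- function(nuSigma = 1, s2Sigma = 1, nuS = 1, s2S = 0.1,
                      muXi = 1, sigma2Xi = 1, aPi = 1, bPi = NULL,
                      expectedAssociations = NULL, m = NULL) {
  if (!is.null(expectedAssociations)) {
    if (is.null(m)) stop("m is required when using expectedAssociations")
    if (expectedAssociations <= 0 || expectedAssociations >= m)
      stop("expectedAssociations must be in (0, m)")
    bPi <- aPi * (m / expectedAssociations - 1)
  }
  if (is.null(bPi)) bPi <- 1
  new("PriorSpec", nuSigma = nuSigma, s2Sigma = s2Sigma, nuS = nuS,
      s2S = s2S, muXi = muXi, sigma2Xi = sigma2Xi, aPi = aPi, bPi = bPi)
}

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec\n",
      sprintf("  sigma^2 ~ Scaled-Inv-chi^2(nu = %g, s2 = %g)\n", object@nuSigma, object@s2Sigma),
      sprintf("  s_j^2   ~ Scaled-Inv-chi^2(nu = %g, s2 = %g)\n", object@nuS, object@s2S),
      sprintf("  xi      ~ Normal(%g, %g)\n", object@muXi, object@sigma2Xi),
      sprintf("  pi      ~ Beta(%g, %g) (integrated to beta-binomial)\n", object@aPi, object@bPi),
      sep = "")
})

#' Construct a RunConfig
#'
#' Defaults follow the conventions of the sampler family: move-size
#' truncation 20, delayed rejection restricted to first-stage moves of size
#' 10 or less, main/swap/toggle kernel mixture 0.7/0.15/0.15 when the locus
#' moves are enabled, every 10th sample kept, first half of the chain as
#' burn-in and adaptation phase.
#'
#' @param iterations,thin,burninFraction,hyperUpdateInterval chain schedule.
#' @param sampler kernel family: \code{"ss"}, \code{"ms"}, \code{"msdr"},
#'   \code{"ksc"} or \code{"nk"}.
#' @param blockK block size for the comparison kernels.
#' @param kernelWeights mixture of (main, swap, neighborhood-toggle) moves.
#' @param kMax,drCutoff,epsMin,pGeomInit proposal constants.
#' @param adaptive,adaptMoveSize adaptation switches.
#' @param rbInterval,weightInterval,moveSizeInterval adaptation schedule.
#' @param neighborhoodCutoff,pSwap,pNeighborhood locus-move settings.
#' @param fixedTau2 optional fixed tau_j^2 vector (freezes the effect-size
#'   variance hierarchy; recycled to m by the runner).
#' @param drAudit independently recompute and record every second-stage
#'   acceptance ratio.
#' @param refactorInterval Cholesky refactorization interval.
#' @param seed master RNG seed.
#' @return a \code{\linkS4class{RunConfig}} object.
#' @examples
#' runConfig(iterations = 1000, sampler = "msdr", seed = 7)
#' @export
runConfig <- function(iterations = 10000L, thin = 10L, burninFraction = 0.5,
                      hyperUpdateInterval = NULL,
                      sampler = c("ms", "ss", "msdr", "ksc", "nk"),
                      blockK = 2L,
                      kernelWeights = c(1, 0, 0),
                      kMax = 20L, drCutoff = 10L, epsMin = NULL,
                      pGeomInit = 0.5,
                      adaptive = TRUE, adaptMoveSize = NULL,
                      rbInterval = 100L, weightInterval = 1000L,
                      moveSizeInterval = 5000L,
                      neighborhoodCutoff = 20L, pSwap = 0.5,
                      pNeighborhood = 0.5,
                      fixedTau2 = numeric(0), drAudit = FALSE,
                      refactorInterval = 1000L, seed = 1L) {
  sampler <- match.arg(sampler)
  if (is.null(hyperUpdateInterval))
    hyperUpdateInterval <- if (sampler %in% c("ksc", "nk")) 100L else 10L
  if (is.null(adaptMoveSize)) adaptMoveSize <- sampler %in% c("ms", "msdr")
  if (is.null(epsMin)) epsMin <- NA_real_  # resolved to 1/m by the runner
  new("RunConfig",
      iterations = as.integer(iterations), thin = as.integer(thin),
      burninFraction = burninFraction,
      hyperUpdateInterval = as.integer(hyperUpdateInterval),
      sampler = sampler, blockK = as.integer(blockK),
      kernelWeights = kernelWeights, kMax = as.integer(kMax),
      drCutoff = as.integer(drCutoff), epsMin = epsMin,
      pGeomInit = pGeomInit, adaptive = adaptive,
      adaptMoveSize = adaptMoveSize,
      rbInterval = as.integer(rbInterval),
      weightInterval = as.integer(weightInterval),
      moveSizeInterval = as.integer(moveSizeInterval),
      neighborhoodCutoff = as.integer(neighborhoodCutoff),
      pSwap = pSwap, pNeighborhood = pNeighborhood,
      fixedTau2 = as.numeric(fixedTau2), drAudit = drAudit,
      refactorInterval = as.integer(refactorInterval),
      seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: sampler=%s iterations=%d thin=%d burnin=%.2f adaptive=%s\n",
              object@sampler, object@iterations, object@thin,
              object@burninFraction, object@adaptive))
})

setMethod("show", "ChainTrace", function(object) {
  kept <- length(object@modelSize)
  cat(sprintf("ChainTrace: %d kept samples of %d variants (%s sampler)\n",
              kept, ncol(object@gammaTrace), object@config@sampler))
  if (kept) {
    post <- object@modelSize[-seq_len(object@burninKept)]
    if (!length(post)) post <- object@modelSize
    cat(sprintf("  post-burnin model size: mean %.2f, range [%d, %d]\n",
                mean(post), min(post), max(post)))
  }
})

#' @describeIn runChain Rao-Blackwellized (default) or empirical posterior
#'   inclusion probabilities from a trace.
#' @param trace a \code{ChainTrace}.
#' @param type \code{"rb"} or \code{"empirical"}.
#' @export
pip <- function(trace, type = c("rb", "empirical")) {
  type <- match.arg(type)
  if (type == "rb") trace@pipRB else trace@pipEmpirical
}

#' @describeIn runChain kept indicator samples after burn-in removal.
#' @export
keptGamma <- function(trace) {
  b <- trace@burninKept
  if (b > 0L) trace@gammaTrace[-seq_len(b), , drop = FALSE] else trace@gammaTrace
}
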