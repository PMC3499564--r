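# Synthetic GWAS generator: LD-blocked genotypes from a thresholded latent
# Gaussian model, double-exponential effect sizes with exact in-sample PVE
# rescaling, and the adversarial "cancelling pair" fixture.

#' Simulation design constructor
#'
#' @param n,m individuals and variants.
#' @param ldBlockLength variants per linkage-disequilibrium block.
#' @param rho latent within-block AR(1) correlation, in [0, 1).
#' @param mafRange minor-allele frequency range, within (0, 0.5].
#' @param nCausal number of causal variants.
#' @param effectScale scale of the double-exponential effect distribution.
#' @param pve target proportion of variance explained, in (0, 1).
#' @return a \code{\linkS4class{SimSpec}}.
#' @examples
#' simSpec(n = 500, m = 50, nCausal = 3)
#' @export
simSpec <- function(n = 2000L, m = 200L, ldBlockLength = 20L, rho = 0.9,
                    mafRange = c(0.05, 0.5), nCausal = 5L,
                    effectScale = 0.3, pve = 0.5) {
  new("SimSpec", n = as.integer(n), m = as.integer(m),
      ldBlockLength = as.integer(ldBlockLength), rho = as.numeric(rho),
      mafRange = as.numeric(mafRange), nCausal = as.integer(nCausal),
      effectScale = as.numeric(effectScale), pve = as.numeric(pve))
}

# one double-exponential (Laplace) sample vector
.rLaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Simulate LD-blocked genotype dosages
#'
#' Each block draws two latent haplotypes per individual from a Gaussian
#' AR(\code{rho}) process along the block; a haplotype carries the minor
#' allele at variant j when its latent value falls below
#' \code{qnorm(maf_j)}, and the dosage is the sum of the two haplotype
#' alleles (Hardy-Weinberg pairing). Per-variant minor-allele frequencies
#' are uniform on \code{mafRange}. Monomorphic columns are resampled with a
#' fresh frequency (keeping the latent structure); a column that stays
#' monomorphic is perturbed at one random individual as a last resort.
#'
#' @param spec a \code{\linkS4class{SimSpec}}.
#' @param seed integer seed; the result is a deterministic function of
#'   \code{(spec, seed)}.
#' @return an n x m integer dosage matrix with values in \{0, 1, 2\},
#'   with the realized minor-allele frequencies in attribute \code{"maf"}.
#' @examples
#' X <- simulateGenotypes(simSpec(n = 100, m = 10), seed = 1)
#' range(X)
#' @export
simulateGenotypes <- function(spec, seed) {
  set.seed(as.integer(seed))
  n <- spec@n; m <- spec@m
  L <- spec@ldBlockLength; rho <- spec@rho
  X <- matrix(0L, n, m)
  maf <- stats::runif(m, spec@mafRange[1], spec@mafRange[2])
  innov <- sqrt(1 - rho^2)
  starts <- seq(1L, m, by = L)
  for (s in starts) {
    cols <- s:min(s + L - 1L, m)
    k <- length(cols)
    # two haplotypes per individual, AR(rho) along the block
    for (h in 1:2) {
      Z <- matrix(0, n, k)
      Z[, 1] <- stats::rnorm(n)
      if (k > 1) for (t in 2:k)
        Z[, t] <- rho * Z[, t - 1] + innov * stats::rnorm(n)
      A <- Z < matrix(stats::qnorm(maf[cols]), n, k, byrow = TRUE)
      X[, cols] <- X[, cols] + A
    }
  }
  # resample monomorphic columns with fresh frequencies
  for (j in seq_len(m)) {
    tries <- 0L
    while (length(unique(X[, j])) == 1L && tries < 20L) {
      maf[j] <- stats::runif(1, max(spec@mafRange[1], 0.1), spec@mafRange[2])
      z <- stats::rnorm(n) < stats::qnorm(maf[j])
      z2 <- stats::rnorm(n) < stats::qnorm(maf[j])
      X[, j] <- as.integer(z) + as.integer(z2)
      tries <- tries + 1L
    }
    if (length(unique(X[, j])) == 1L) {  # last resort: flip one genotype
      i <- sample.int(n, 1)
      X[i, j] <- if (X[i, j] == 0L) 1L else 0L
    }
  }
  storage.mode(X) <- "integer"
  colnames(X) <- sprintf("snp%d", seq_len(m))
  attr(X, "maf") <- maf
  X
}

#' Simulate a phenotype with exact in-sample PVE
#'
#' Draws \code{nCausal} causal variants uniformly, effect sizes from the
#' double-exponential distribution with scale \code{effectScale}, and
#' Gaussian noise rescaled so the realized in-sample proportion of variance
#' explained equals \code{spec@pve} exactly:
#' the noise vector is scaled to variance
#' \code{var(signal) * (1 - pve) / pve}.
#'
#' @param X genotype dosage matrix (columns in genomic order).
#' @param spec a \code{\linkS4class{SimSpec}}.
#' @param seed integer seed.
#' @return list with \code{y} (phenotype) and \code{truth} (list with
#'   \code{causal} indices, \code{effects}, and \code{pveRealized}).
#' @examples
#' sp <- simSpec(n = 200, m = 20, nCausal = 2)
#' X <- simulateGenotypes(sp, seed = 1)
#' sim <- simulatePhenotype(X, sp, seed = 2)
#' sim$truth$pveRealized
#' @export
simulatePhenotype <- function(X, spec, seed) {
  if (spec@pve <= 0 || spec@pve >= 1) stop("pve must lie in (0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(X); m <- ncol(X)
  if (spec@nCausal > m) stop("nCausal must be <= m")
  causal <- sort(sample.int(m, spec@nCausal))
  effects <- .rLaplace(spec@nCausal, spec@effectScale)
  signal <- as.vector(X[, causal, drop = FALSE] %*% effects)
  vSig <- stats::var(signal)
  if (vSig == 0) stop("degenerate signal: causal columns carry no variance")
  eps <- stats::rnorm(n)
  # orthogonalize against the signal and rescale so the in-sample PVE is exact
  eps <- stats::residuals(stats::lm(eps ~ signal))
  eps <- eps * sqrt(vSig * (1 - spec@pve) / spec@pve / stats::var(eps))
  y <- signal + eps
  pveRealized <- vSig / stats::var(y)
  list(y = y,
       truth = list(causal = causal, effects = effects,
                    pveRealized = pveRealized))
}

#' Adversarial cancelling-pair fixture
#'
#' Builds a dataset in which two highly correlated adjacent variants carry
#' large opposite-signed coefficients whose marginal effects nearly cancel:
#' each is individually non-significant (|t| below \code{tMax}) while the
#' joint two-variant model is overwhelmingly significant (F-test p-value
#' below \code{fMax}). Generation asserts both properties and retries with
#' fresh noise until they hold.
#'
#' @param n,m individuals and variants (m >= 3).
#' @param seed integer seed.
#' @param tMax marginal |t| bound asserted for each pair member.
#' @param fMax joint F-test p-value bound asserted for the pair.
#' @param maxTries generation attempts before giving up with an error.
#' @return list with \code{X} (dosages), \code{y}, and \code{truth} (list
#'   with \code{pair} (the two column indices), \code{effects}, marginal
#'   t statistics and the joint F p-value).
#' @examples
#' trap <- makePairTrap(n = 500, m = 20, seed = 1)
#' trap$truth$pair
#' @export
makePairTrap <- function(n = 2000L, m = 200L, seed = 1L, tMax = 2,
                         fMax = 1e-6, maxTries = 50L) {
  if (m < 3L) stop("m must be >= 3")
  sp <- simSpec(n = n, m = m, nCausal = 1L, pve = 0.2)
  X <- simulateGenotypes(sp, seed = seed)
  j1 <- as.integer(m %/% 2); j2 <- j1 + 1L
  x1 <- X[, j1]
  b <- 1
  for (tries in seq_len(maxTries)) {
    # manufacture a tightly correlated adjacent pair in the middle block;
    # each retry redraws both the disagreement pattern and the noise
    set.seed(as.integer(seed) + 1000003L * tries)
    x2 <- x1
    flip <- sample.int(n, max(2L, round(0.05 * n)))
    # re-randomize from x1's own genotype distribution, keeping the two
    # members' covariances with the difference symmetric at any frequency
    x2[flip] <- sample(x1, length(flip), replace = TRUE)
    X[, j2] <- x2
    d <- x1 - x2          # the near-cancelling combination
    eps <- stats::rnorm(n)
    # each member still covaries with d, and its marginal t grows like
    # sqrt(n) * cov(x_j, bd) / (sd(x_j) sd(y)); scale the noise so the
    # expected marginal |t| is about 1 while the joint signal stays huge
    sdYNeeded <- sqrt(n) / 1.4 *
      max(abs(stats::cov(x1, b * d)) / stats::sd(x1),
          abs(stats::cov(x2, b * d)) / stats::sd(x2))
    sdNoise <- max(sqrt(max(sdYNeeded^2 - stats::var(b * d), 0)),
                   stats::sd(b * d) * 1.2, 1e-8)
    y <- b * x1 - b * x2 + sdNoise * (eps - mean(eps)) / stats::sd(eps)
    tMarg <- vapply(c(j1, j2), function(j) {
      fit <- stats::lm(y ~ X[, j])
      summary(fit)$coefficients[2, 3]
    }, numeric(1))
    fit2 <- stats::lm(y ~ X[, j1] + X[, j2])
    fit0 <- stats::lm(y ~ 1)
    an <- stats::anova(fit0, fit2)
    pJoint <- an[["Pr(>F)"]][2]
    if (all(abs(tMarg) < tMax) && pJoint < fMax) {
      return(list(X = X, y = y,
                  truth = list(pair = c(j1, j2), effects = c(b, -b),
                               tMarginal = tMarg, pJoint = pJoint)))
    }
  }
  stop("failed to construct a cancelling pair within maxTries attempts")
}
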