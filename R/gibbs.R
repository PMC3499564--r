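# Five-step Gibbs scheme with the sign-flip move, kernel mixing, finite
# adaptation, thinning and trace recording.  The indicator update (step 3)
# runs in the compiled engine; the hyperparameter sweep, adaptation and
# bookkeeping remain in R, and the delayed-rejection audit recomputes every
# second-stage acceptance ratio from scratch in R.

# scaled-inverse-chi-square draw(s): nu * s2 / chisq_nu
.rScInvChisq <- function(n, nu, s2) nu * s2 / stats::rchisq(n, nu)

# one named RNG stream per sub-kernel, derived from the master seed, so
# enabling or disabling one kernel does not perturb the others' draws
.streamsNew <- function(seed, names) {
  streams <- new.env(parent = emptyenv())
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, length(names))
  for (i in seq_along(names)) {
    set.seed(subSeeds[i])
    streams[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  streams
}

.useStream <- function(streams, name, fun) {
  assign(".Random.seed", streams[[name]], envir = globalenv())
  res <- fun()
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  res
}

# fingerprint of every proposal parameter the kernels read
.psHash <- function(ps) {
  paste(format(c(ps$addW, ps$removeW, ps$pGeom, as.numeric(ps$kMax)),
               digits = 17), collapse = ",")
}

# sign-flip Metropolis move on (xi, b); beta = xi * b is invariant when the
# flip is accepted
.signFlipMove <- function(xi, prior) {
  if (xi == 0) return(list(flip = FALSE, xi = xi))
  sdXi <- sqrt(prior@sigma2Xi)
  logA <- stats::dnorm(-xi, prior@muXi, sdXi, log = TRUE) -
    stats::dnorm(xi, prior@muXi, sdXi, log = TRUE)
  flip <- logA >= 0 || stats::runif(1) < exp(logA)
  list(flip = flip, xi = if (flip) -xi else xi)
}

#' Run the adaptive spike-and-slab sampler
#'
#' The five-step Gibbs scheme: (1) variance components s_j^2, (2) expansion
#' scalar xi followed by the sign-flip move, (3) indicator
#' Metropolis-Hastings update, (4) residual variance sigma^2, (5) regression
#' coefficients. Step 3 runs every iteration; the others every
#' \code{hyperUpdateInterval}-th iteration. Proposal adaptation (weights
#' from Rao-Blackwellized inclusion probabilities, move-size parameter by
#' expected jump distance) runs during burn-in only and is frozen at its
#' end, so the sampling-phase chain is a fixed-kernel Markov chain; the
#' fingerprints of the proposal parameters observed after the freeze are
#' recorded in the trace.
#'
#' When \code{fixedTau2} is set in the configuration, the effect-variance
#' hierarchy (steps 1-2 and the sign flip) is frozen at tau_j^2 =
#' \code{fixedTau2} and the indicator chain targets the enumerable
#' fixed-variance posterior; sigma^2 and the coefficients are still drawn
#' for the trace and the Rao-Blackwellized estimator.
#'
#' @param data a \code{\linkS4class{GwasData}}.
#' @param prior a \code{\linkS4class{PriorSpec}}.
#' @param config a \code{\linkS4class{RunConfig}}.
#' @return a \code{\linkS4class{ChainTrace}}.
#' @examples
#' set.seed(2)
#' gd <- gwasData(matrix(rbinom(200, 2, 0.4), 50, 4), rnorm(50))
#' tr <- runChain(gd, priorSpec(), runConfig(iterations = 200, seed = 5))
#' pip(tr)
#' @export
runChain <- function(data, prior, config) {
  m <- nVariants(data); n <- nSamples(data)
  cfg <- config
  epsMin <- if (is.na(cfg@epsMin)) 1 / m else cfg@epsMin
  fixedTau <- length(cfg@fixedTau2) > 0L

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  streams <- .streamsNew(cfg@seed, c("mix", "main", "swap", "nbr", "hyper"))

  ps <- .proposalStateNew(m, epsMin, cfg@pGeomInit, cfg@kMax, cfg@drCutoff)
  X <- data@X
  storage.mode(X) <- "double"
  cst <- .Call("C_state_new", X, as.numeric(data@y),
               as.numeric(data@columnSqNorms), prior@aPi, prior@bPi,
               prior@nuSigma, prior@s2Sigma, as.integer(data@snpOrder),
               as.integer(cfg@refactorInterval))
  orderPos <- as.integer(data@snpOrder)
  orderVar <- order(data@snpOrder)

  est <- .rbEstimatorNew(m, prior@aPi, prior@bPi)
  doRB <- cfg@adaptive || cfg@sampler == "nk"
  nkPip <- est$pipHat   # NK proposal probabilities; snapshot frozen at burn-in end

  # initial hyperparameter state
  beta <- numeric(m)   # effects beta_j = xi * b_j (zero where excluded)
  init <- .useStream(streams, "hyper", function() {
    s2 <- .rScInvChisq(m, prior@nuS, prior@s2S)
    xi <- stats::rnorm(1, prior@muXi, sqrt(prior@sigma2Xi))
    sigma2 <- .rScInvChisq(1, prior@nuSigma, prior@s2Sigma)
    list(s2 = s2, xi = xi, sigma2 = sigma2)
  })
  s2 <- init$s2; xi <- init$xi; sigma2 <- init$sigma2
  if (fixedTau) {
    tau2full <- rep_len(as.numeric(cfg@fixedTau2), m)
    if (any(tau2full <= 0)) stop("fixedTau2 must be positive")
    xi <- NA_real_
  } else {
    tau2full <- pmax(xi^2 * s2, 1e-300)
  }
  .Call("C_state_set_tau2", cst, tau2full)

  iters <- cfg@iterations
  burnIter <- as.integer(floor(iters * cfg@burninFraction))
  nKept <- iters %/% cfg@thin
  gammaTrace <- matrix(0L, nKept, m)
  msTrace <- numeric(nKept); s2Trace <- numeric(nKept)
  xiTrace <- numeric(nKept); pveTrace <- numeric(nKept)
  lpTrace <- numeric(nKept)
  recKernel <- character(iters); recKProp <- integer(iters)
  recKDrawn <- integer(iters); recJump <- integer(iters)
  recAcc <- logical(iters); recA <- numeric(iters)
  recDr <- logical(iters); recDrRatio <- rep(NA_real_, iters)
  recPUsed <- numeric(iters)

  mainMode <- match(cfg@sampler, c("ss", "ms", "msdr")) - 1L  # NA for ksc/nk
  cutoff <- as.integer(cfg@neighborhoodCutoff)
  gammaLog <- logical(m)

  varY <- stats::var(data@y)
  kept <- 0L
  step3Seconds <- 0
  psHashes <- character(0)
  lastHash <- NULL
  pGeomFinal <- ps$pGeom
  if (burnIter == 0L) { ps$frozen <- TRUE }
  wMix <- cumsum(cfg@kernelWeights)

  for (i in seq_len(iters)) {
    sweepNow <- i %% cfg@hyperUpdateInterval == 0L
    if (sweepNow && !fixedTau) {
      # steps 1-2 and the sign flip
      res <- .useStream(streams, "hyper", function() {
        b <- beta / xi
        dfS <- prior@nuS + as.numeric(gammaLog)
        scS <- ifelse(gammaLog,
                      (prior@nuS * prior@s2S + (b^2) / sigma2) / (prior@nuS + 1),
                      prior@s2S)
        s2new <- dfS * scS / stats::rchisq(m, dfS)
        cvec <- if (any(gammaLog))
          as.vector(X[, gammaLog, drop = FALSE] %*% b[gammaLog])
        else numeric(n)
        prec <- sum(cvec^2) / sigma2 + 1 / prior@sigma2Xi
        mu <- (sum(cvec * data@y) / sigma2 + prior@muXi / prior@sigma2Xi) / prec
        xiNew <- stats::rnorm(1, mu, sqrt(1 / prec))
        fl <- .signFlipMove(xiNew, prior)
        list(s2 = s2new, xi = fl$xi)
      })
      s2 <- res$s2; xi <- res$xi
      if (!is.finite(xi) || any(!is.finite(s2)))
        stop(sprintf("non-finite hyperparameter draw at iteration %d", i))
      tau2full <- pmax(xi^2 * s2, 1e-300)
      .Call("C_state_set_tau2", cst, tau2full)
    }

    # step 3: indicator update, timed separately
    t0 <- proc.time()[[3L]]
    recPUsed[i] <- ps$pGeom
    u <- .useStream(streams, "mix", function() stats::runif(1))
    kernelPick <- findInterval(u, wMix) + 1L   # 1 main, 2 swap, 3 toggle
    rec <- if (kernelPick == 2L) {
      .useStream(streams, "swap", function()
        .Call("C_swap_step", cst, cutoff, cfg@pSwap, ps$kMax))
    } else if (kernelPick == 3L) {
      .useStream(streams, "nbr", function()
        .Call("C_nbr_step", cst, cutoff, cfg@pNeighborhood, ps$kMax,
              cfg@sampler == "msdr", ps$drCutoff, ps$addW, ps$removeW,
              ps$pGeom, isTRUE(cfg@drAudit)))
    } else {
      .useStream(streams, "main", function() {
        if (!is.na(mainMode))
          .Call("C_main_step", cst, ps$addW, ps$removeW, ps$pGeom, ps$kMax,
                ps$drCutoff, mainMode, isTRUE(cfg@drAudit), cutoff,
                cfg@pNeighborhood)
        else if (cfg@sampler == "ksc")
          .Call("C_ksc_step", cst, cfg@blockK)
        else
          .Call("C_nk_step", cst, cfg@blockK, nkPip, epsMin)
      })
    }
    info <- .Call("C_state_info", cst)
    gammaLog <- logical(m); gammaLog[info$incl] <- TRUE
    step3Seconds <- step3Seconds + (proc.time()[[3L]] - t0)
    recKernel[i] <- rec$kernel; recKProp[i] <- rec$kProposed
    recKDrawn[i] <- rec$kDrawn
    recJump[i] <- rec$jump; recAcc[i] <- rec$accepted; recA[i] <- rec$accProb
    recDr[i] <- rec$drUsed
    if (isTRUE(cfg@drAudit) && !is.null(rec$detail)) {
      stMirror <- list(m = m, n = n, tau2full = tau2full, inModel = gammaLog,
                       orderPos = orderPos, orderVar = orderVar)
      recDrRatio[i] <- .drAuditFromDetail(data, prior, cfg, ps, stMirror,
                                          rec$detail)
    }

    if (sweepNow) {
      # steps 4-5: sigma^2 and the coefficients given the new gamma
      res <- .useStream(streams, "hyper", function() {
        S <- info$S
        sig2 <- (prior@nuSigma * prior@s2Sigma + S) /
          stats::rchisq(1, prior@nuSigma + n - 1)
        bIncl <- .Call("C_beta_draw", cst, sig2)
        list(sigma2 = sig2, bIncl = bIncl)
      })
      sigma2 <- res$sigma2
      if (!is.finite(sigma2) || any(!is.finite(res$bIncl)))
        stop(sprintf("non-finite conditional draw at iteration %d", i))
      beta <- numeric(m)
      if (length(info$incl)) beta[info$incl] <- res$bIncl
    }

    # Rao-Blackwellized estimator update
    if (doRB && i %% cfg@rbInterval == 0L)
      .rbUpdate(est, rbConditionalPip(data, prior, gammaLog, beta,
                                      sigma2, tau2full))

    # finite adaptation (burn-in only)
    if (!ps$frozen) {
      if (cfg@adaptive && cfg@sampler %in% c("ss", "ms", "msdr") &&
          i %% cfg@weightInterval == 0L)
        .adaptWeights(ps, est$pipHat)
      if (cfg@adaptMoveSize && i %% cfg@moveSizeInterval == 0L) {
        sel <- which(recKDrawn[seq_len(i)] >= 1L &
                       recKernel[seq_len(i)] %in% c("ss", "ms", "msdr"))
        if (length(sel)) {
          # per-move expected-jump contribution k * a: for ss/ms the
          # Rao-Blackwellized first-stage probability, for msdr the
          # realized jump so that delayed-rejection rescues (which move
          # fewer than k indicators but more than zero) are credited
          aEff <- ifelse(recKernel[sel] == "msdr",
                         recJump[sel] / recKDrawn[sel], recA[sel])
          ps$pGeom <- adaptMoveSize(list(k = recKDrawn[sel], a = aEff,
                                         pUsed = recPUsed[sel]),
                                    kMax = cfg@kMax)
        }
      }
      if (cfg@sampler == "nk") nkPip <- est$pipHat
      if (i >= burnIter) {
        ps$frozen <- TRUE
        pGeomFinal <- ps$pGeom
        # reported RB estimates restart so they average the sampling phase
        est <- .rbEstimatorNew(m, prior@aPi, prior@bPi)
      }
    } else {
      h <- .psHash(ps)
      if (is.null(lastHash) || !identical(h, lastHash)) {
        psHashes <- c(psHashes, h)
        lastHash <- h
      }
    }

    if (i %% cfg@thin == 0L) {
      kept <- kept + 1L
      gammaTrace[kept, ] <- as.integer(gammaLog)
      msTrace[kept] <- info$q
      s2Trace[kept] <- sigma2
      xiTrace[kept] <- xi
      lpTrace[kept] <- info$logpost
      pveTrace[kept] <- if (info$q > 0L) {
        fitted <- as.vector(X[, info$incl, drop = FALSE] %*% beta[info$incl])
        stats::var(fitted) / varY
      } else 0
    }
  }

  burninKept <- burnIter %/% cfg@thin
  post <- if (burninKept > 0L)
    gammaTrace[-seq_len(burninKept), , drop = FALSE] else gammaTrace
  pipEmp <- if (nrow(post)) colMeans(post) else rep(NA_real_, m)

  moveRecords <- data.frame(
    kernel = recKernel, kProposed = recKProp, kDrawn = recKDrawn,
    jump = recJump, accepted = recAcc, accProb = recA,
    drUsed = recDr, drRatio = recDrRatio, pUsed = recPUsed,
    stringsAsFactors = FALSE)

  new("ChainTrace",
      gammaTrace = gammaTrace, modelSize = msTrace, sigma2 = s2Trace,
      xi = xiTrace, pve = pveTrace, logPost = lpTrace,
      moveRecords = moveRecords, pipRB = est$pipHat, pipEmpirical = pipEmp,
      pGeomFinal = pGeomFinal, psHash = unique(psHashes),
      step3Seconds = step3Seconds, burninKept = as.integer(burninKept),
      config = cfg)
}
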