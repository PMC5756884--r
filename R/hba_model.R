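# The hierarchical Bayesian analog model: Poisson data model, bias-corrected
# truncated-normal process model on the NMF coefficients, discrete-uniform /
# inverse-gamma parameter model, Metropolis-Hastings sampler, and
# posterior-predictive forecasting.

#' Truncated-normal process log density of a coefficient vector
#'
#' The process model: given the other periods' coefficients `Bminus` and
#' analog weights `w`, the coefficient vector for a period is truncated
#' normal on `[0, Inf)` with location `max(h(Bminus w, sigma2), eps)`
#' elementwise — the bias-corrected ([biasCorrectH()]) weighted-analog
#' prediction, floored at `eps` — and scale `sigma2` per coordinate.
#' Coordinates where the weighted prediction is nonpositive (possible only if
#' every analog coefficient is zero) take location `eps` directly.
#'
#' @param beta nonnegative coefficient vector (length = rank); any negative
#'   entry puts the vector outside the support and returns `-Inf`.
#' @param Bminus rank x (pool - 1) matrix of the other periods' coefficients.
#' @param w analog weight vector over those periods (sums to 1).
#' @param sigma2 process variance.
#' @param eps location floor.
#' @return the log density, summed over coordinates.
#' @export
processLogDensity <- function(beta, Bminus, w, sigma2, eps = 1e-6) {
    if (any(beta < 0)) return(-Inf)
    a <- drop(as.matrix(Bminus) %*% w)
    mu <- tnProcessMean(a, sigma2, eps)
    sum(tnLogDensity(beta, mu, sigma2))
}

#' Poisson data log density
#'
#' Sum of Poisson log probabilities of observed counts given site
#' intensities. A zero intensity contributes 0 when the count is zero and
#' `-Inf` otherwise.
#'
#' @param y nonnegative integer count vector.
#' @param lambda nonnegative intensity vector of the same length.
#' @return the summed log probability.
#' @export
dataLogDensity <- function(y, lambda) {
    if (any(y != round(y)) || any(y < 0))
        stop("counts must be nonnegative integers")
    if (any(lambda < 0)) stop("lambda must be nonnegative")
    sum(dpois(y, lambda, log = TRUE))
}

# ---- sampler internals -----------------------------------------------------

logPriorIG <- function(x, a, b) -(a + 1) * log(x) - b / x

# per-period process log densities for all pool periods at once
procTermsAll <- function(B, mu, sigma2) {
    s <- sqrt(sigma2)
    colSums(dnorm(B, mu, s, log = TRUE) -
            pnorm(mu / s, log.p = TRUE))
}

dataTermsAll <- function(Y, Psi, B, bOff) {
    lam <- Psi %*% B + bOff
    colSums(dpois(Y, lam, log = TRUE))
}

neighborList <- function(W) {
    lapply(seq_len(ncol(W)), function(t) which(W[, t] > 0))
}

#' Fit the hierarchical Bayesian analog model by MCMC
#'
#' Metropolis-Hastings sampling of the embedding depth q and neighborhood
#' size m (discrete random walk on `{x-1, x, x+1}` intersected with the prior
#' support, with the boundary-corrected Hastings ratio), the kernel parameter
#' theta1 and process variance sigma2eta (log-scale Gaussian random walks,
#' s.d. 0.2), the Laplacian-eigenmap neighbor count over its grid (when the
#' cache holds one), and optionally every period's coefficient vector beta_t
#' by a coordinatewise truncated-normal random walk whose proposal scale is
#' tuned during burn-in toward a 20-50% acceptance rate and then frozen.
#' Coefficient sampling is off by default: the process model specifies each
#' period's coefficients conditionally on all the others, and the product of
#' those conditionals — the only joint available — rewards configurations
#' where every beta_t equals its weighted-analog prediction exactly, so a
#' chain that samples B drifts there and the process variance collapses
#' toward zero. With B frozen at the factorization estimate the remaining
#' parameters are well identified.
#'
#' Training weights for period t exclude only period t itself, so
#' analogs may come from both past and future training periods; forecasts use
#' past periods only by construction of the pool. The chain is a
#' deterministic function of `seed`.
#'
#' @param counts a [SpaceTimeCounts-class] or count matrix (sites x periods).
#' @param factorization an [NMFFactorization-class] of those counts.
#' @param cache a [DistanceCache-class] covering `hyper@qMin:hyper@qMax`.
#' @param hyper an [HBAHyperParams-class].
#' @param nIter,burnIn total and burn-in iteration counts (reference
#'   analysis: 20000 / 2000).
#' @param seed integer RNG seed.
#' @param sampleB sample the coefficient matrix (default FALSE; see
#'   Details for why sampling B is degenerate under the pseudo-joint).
#' @param likelihood `"full"` for the posterior; `"prior"` drops the data and
#'   process terms so the chain targets the parameter model alone (a sampler
#'   correctness check: the q margin must then be discrete uniform).
#' @param holdout integer period indices (into the cache pool's period
#'   numbering) removed from the training likelihood and analog pool, for
#'   hindcast experiments.
#' @param thin retain every `thin`-th post-burn-in draw (default 1). Useful
#'   for near-independent draws from the discrete random walks when testing
#'   marginal distributions.
#' @return an [HBAPosterior-class].
#' @export
hbaFit <- function(counts, factorization, cache, hyper = HBAHyperParams(),
                   nIter = 20000L, burnIn = 2000L, seed = 1L,
                   sampleB = FALSE, likelihood = c("full", "prior"),
                   holdout = integer(0), thin = 1L) {
    likelihood <- match.arg(likelihood)
    useData <- likelihood == "full"
    set.seed(seed)
    Yfull <- if (is(counts, "SpaceTimeCounts")) counts(counts)
             else as.matrix(counts)
    pool <- setdiff(cache@pool, holdout)
    if (length(holdout)) {
        # rebuild a pool-restricted view of the cache
        keep <- match(pool, cache@pool)
        cache <- subsetCachePool(cache, keep)
    }
    Y <- Yfull[, pool, drop = FALSE]
    Psi <- basisMatrix(factorization)
    bOff <- offsetVector(factorization)
    B <- coefMatrix(factorization)[, pool, drop = FALSE]
    nb <- nrow(B); n <- ncol(B)
    if (n < hyper@mMax + 1L)
        stop("analog pool must exceed mMax")
    qs <- hyper@qMin:hyper@qMax
    if (!all(paste0("q", qs) %in% names(cache@dists[[1L]])))
        stop("cache does not cover the q prior support")
    leGrid <- cache@leGrid
    useLE <- length(leGrid) > 0L

    # initial state: range midpoints, prior mean, small process variance
    q <- as.integer(round((hyper@qMin + hyper@qMax) / 2))
    m <- as.integer(round((hyper@mMin + hyper@mMax) / 2))
    th1 <- if (hyper@a1 > 1) hyper@b1 / (hyper@a1 - 1) else hyper@b1
    s2 <- 0.01
    le <- if (useLE) leGrid[1L] else NA_integer_
    W <- A <- mu <- NULL
    procT <- dataT <- numeric(n)
    nbl <- NULL
    refreshProcess <- function() {
        W <<- weightMatrix(cache, q, m, th1, le)
        nbl <<- neighborList(W)
        A <<- B %*% t(W)
        mu <<- tnProcessMean(A, s2, hyper@eps)
        procT <<- procTermsAll(B, mu, s2)
    }
    if (useData) {
        refreshProcess()
        dataT <- dataTermsAll(Y, Psi, B, bOff)
        if (!all(is.finite(procT)))
            stop("non-finite process density at initialization (period ",
                 which(!is.finite(procT))[1L], ")")
        if (!all(is.finite(dataT)))
            stop("non-finite data density at initialization (period ",
                 which(!is.finite(dataT))[1L], ")")
    }

    thin <- as.integer(thin)
    nKeep <- (nIter - burnIn) %/% thin
    out <- list(q = integer(nKeep), m = integer(nKeep),
                th1 = numeric(nKeep), s2 = numeric(nKeep),
                le = integer(nKeep), lj = numeric(nKeep))
    Bdraws <- if (sampleB && useData)
        array(0, c(nb, n, nKeep)) else array(B, c(nb, n, 1L))
    acc <- c(q = 0, m = 0, theta1 = 0, sigma2eta = 0, le = 0, B = 0)
    tot <- c(q = 0, m = 0, theta1 = 0, sigma2eta = 0, le = 0, B = 0)
    stepB <- rep(0.05 + 0.1 * mean(B), n)
    accB <- totB <- numeric(n)
    rwSD <- 0.2

    discreteStep <- function(x, lo, hi) {
        s <- max(x - 1L, lo):min(x + 1L, hi)
        list(prop = s[sample.int(length(s), 1L)], size = length(s))
    }
    propSize <- function(x, lo, hi) min(x + 1L, hi) - max(x - 1L, lo) + 1L

    for (it in seq_len(nIter)) {
        ## q ------------------------------------------------------------
        st <- discreteStep(q, hyper@qMin, hyper@qMax)
        tot["q"] <- tot["q"] + 1
        if (useData) {
            Wp <- weightMatrix(cache, st$prop, m, th1, le)
            Ap <- B %*% t(Wp)
            mup <- tnProcessMean(Ap, s2, hyper@eps)
            procTp <- procTermsAll(B, mup, s2)
            lr <- sum(procTp) - sum(procT) +
                log(st$size) - log(propSize(st$prop, hyper@qMin, hyper@qMax))
        } else {
            lr <- log(st$size) - log(propSize(st$prop, hyper@qMin, hyper@qMax))
        }
        if (log(runif(1)) < lr) {
            q <- st$prop
            acc["q"] <- acc["q"] + 1
            if (useData) {
                W <- Wp; A <- Ap; mu <- mup; procT <- procTp
                nbl <- neighborList(W)
            }
        }
        ## m ------------------------------------------------------------
        st <- discreteStep(m, hyper@mMin, hyper@mMax)
        tot["m"] <- tot["m"] + 1
        if (useData) {
            Wp <- weightMatrix(cache, q, st$prop, th1, le)
            Ap <- B %*% t(Wp)
            mup <- tnProcessMean(Ap, s2, hyper@eps)
            procTp <- procTermsAll(B, mup, s2)
            lr <- sum(procTp) - sum(procT) +
                log(st$size) - log(propSize(st$prop, hyper@mMin, hyper@mMax))
        } else {
            lr <- log(st$size) - log(propSize(st$prop, hyper@mMin, hyper@mMax))
        }
        if (log(runif(1)) < lr) {
            m <- st$prop
            acc["m"] <- acc["m"] + 1
            if (useData) {
                W <- Wp; A <- Ap; mu <- mup; procT <- procTp
                nbl <- neighborList(W)
            }
        }
        ## theta1 --------------------------------------------------------
        th1p <- th1 * exp(rnorm(1, 0, rwSD))
        tot["theta1"] <- tot["theta1"] + 1
        lr <- logPriorIG(th1p, hyper@a1, hyper@b1) -
              logPriorIG(th1, hyper@a1, hyper@b1) + log(th1p) - log(th1)
        if (useData) {
            Wp <- weightMatrix(cache, q, m, th1p, le)
            Ap <- B %*% t(Wp)
            mup <- tnProcessMean(Ap, s2, hyper@eps)
            procTp <- procTermsAll(B, mup, s2)
            lr <- lr + sum(procTp) - sum(procT)
        }
        if (log(runif(1)) < lr) {
            th1 <- th1p
            acc["theta1"] <- acc["theta1"] + 1
            if (useData) {
                W <- Wp; A <- Ap; mu <- mup; procT <- procTp
                nbl <- neighborList(W)
            }
        }
        ## sigma2eta ------------------------------------------------------
        s2p <- s2 * exp(rnorm(1, 0, rwSD))
        tot["sigma2eta"] <- tot["sigma2eta"] + 1
        lr <- logPriorIG(s2p, hyper@a2, hyper@b2) -
              logPriorIG(s2, hyper@a2, hyper@b2) + log(s2p) - log(s2)
        if (useData) {
            mup <- tnProcessMean(A, s2p, hyper@eps)
            procTp <- procTermsAll(B, mup, s2p)
            lr <- lr + sum(procTp) - sum(procT)
        }
        if (log(runif(1)) < lr) {
            s2 <- s2p
            acc["sigma2eta"] <- acc["sigma2eta"] + 1
            if (useData) { mu <- mup; procT <- procTp }
        }
        ## LE neighbor count ----------------------------------------------
        if (useLE) {
            lep <- leGrid[sample.int(length(leGrid), 1L)]
            tot["le"] <- tot["le"] + 1
            if (useData) {
                Wp <- weightMatrix(cache, q, m, th1, lep)
                Ap <- B %*% t(Wp)
                mup <- tnProcessMean(Ap, s2, hyper@eps)
                procTp <- procTermsAll(B, mup, s2)
                lr <- sum(procTp) - sum(procT)
            } else lr <- 0
            if (log(runif(1)) < lr) {
                le <- lep
                acc["le"] <- acc["le"] + 1
                if (useData) {
                    W <- Wp; A <- Ap; mu <- mup; procT <- procTp
                    nbl <- neighborList(W)
                }
            }
        }
        ## coefficient blocks ---------------------------------------------
        if (sampleB && useData) {
            for (t in seq_len(n)) {
                bOld <- B[, t]
                s <- stepB[t]
                bNew <- rtnorm0(nb, bOld, s * s)
                hast <- sum(pnorm(bOld / s, log.p = TRUE) -
                            pnorm(bNew / s, log.p = TRUE))
                dataTp <- sum(dpois(Y[, t], Psi %*% bNew + bOff, log = TRUE))
                procOwn <- sum(tnLogDensity(bNew, mu[, t], s2))
                ns <- nbl[[t]]
                if (length(ns)) {
                    Ap <- A[, ns, drop = FALSE] +
                        (bNew - bOld) %o% W[ns, t]
                    mup <- tnProcessMean(Ap, s2, hyper@eps)
                    procNb <- colSums(
                        dnorm(B[, ns, drop = FALSE], mup, sqrt(s2),
                              log = TRUE) - pnorm(mup / sqrt(s2),
                                                  log.p = TRUE))
                    dProc <- sum(procNb) - sum(procT[ns])
                } else dProc <- 0
                lr <- (dataTp - dataT[t]) + (procOwn - procT[t]) + dProc +
                    hast
                totB[t] <- totB[t] + 1
                if (log(runif(1)) < lr) {
                    accB[t] <- accB[t] + 1
                    B[, t] <- bNew
                    dataT[t] <- dataTp
                    procT[t] <- procOwn
                    if (length(ns)) {
                        A[, ns] <- Ap
                        mu[, ns] <- mup
                        procT[ns] <- procNb
                    }
                }
            }
            # adapt proposal scales during burn-in, then freeze
            if (it <= burnIn && it %% 50L == 0L) {
                rate <- accB / pmax(totB, 1)
                stepB <- stepB * exp(0.25 * (rate > 0.5) -
                                     0.25 * (rate < 0.2))
                accB[] <- 0; totB[] <- 0
            }
            if (it == burnIn) {      # refresh caches before retention
                refreshProcess()
                dataT <- dataTermsAll(Y, Psi, B, bOff)
            }
        }
        ## retain ---------------------------------------------------------
        if (it > burnIn && (it - burnIn) %% thin == 0L) {
            k <- (it - burnIn) %/% thin
            out$q[k] <- q; out$m[k] <- m
            out$th1[k] <- th1; out$s2[k] <- s2
            out$le[k] <- le
            prior <- logPriorIG(th1, hyper@a1, hyper@b1) +
                logPriorIG(s2, hyper@a2, hyper@b2)
            out$lj[k] <- sum(procT) + sum(dataT) + prior
            if (sampleB && useData) Bdraws[, , k] <- B
        }
    }
    rates <- acc / pmax(tot, 1)
    rates["B"] <- if (sampleB && useData)
        sum(accB) / max(sum(totB), 1) else NA_real_
    if (!useLE) rates <- rates[names(rates) != "le"]
    new("HBAPosterior", q = out$q, m = out$m, theta1 = out$th1,
        sigma2eta = out$s2,
        leK = if (useLE) out$le else integer(0),
        B = Bdraws, logJoint = out$lj, acceptRates = rates, hyper = hyper,
        pool = as.integer(pool), seed = as.integer(seed))
}

# restrict a DistanceCache to a subset of its pool rows/columns
subsetCachePool <- function(cache, keep) {
    n <- length(keep)
    redo <- function(dq) {
        lapply(dq, function(d) d[keep, keep, drop = FALSE])
    }
    dists <- lapply(cache@dists, redo)
    sortIdx <- sortD <- vector("list", length(dists))
    for (g in seq_along(dists)) {
        si <- sd <- list()
        for (key in names(dists[[g]])) {
            d <- dists[[g]][[key]]
            s1 <- matrix(0L, n, n - 1L)
            s2 <- matrix(0, n, n - 1L)
            for (i in seq_len(n)) {
                o <- order(d[i, -i])
                s1[i, ] <- (seq_len(n)[-i])[o]
                s2[i, ] <- (d[i, -i])[o]
            }
            si[[key]] <- s1; sd[[key]] <- s2
        }
        sortIdx[[g]] <- si; sortD[[g]] <- sd
    }
    names(sortIdx) <- names(sortD) <- names(dists)
    targetD <- lapply(cache@targetD, function(tq)
        lapply(tq, function(tm) tm[, keep, drop = FALSE]))
    targetSortIdx <- lapply(targetD, function(tq)
        lapply(tq, function(tm) t(apply(tm, 1L, order))))
    new("DistanceCache", dists = dists, sortIdx = sortIdx, sortD = sortD,
        targetD = targetD, targetSortIdx = targetSortIdx,
        pool = cache@pool[keep], qRange = cache@qRange,
        leGrid = cache@leGrid, theta2 = cache@theta2,
        targets = cache@targets)
}

#' Posterior-predictive analog forecast
#'
#' For each retained draw, forms forecast weights over all pool periods from
#' the cached target-to-pool distances with that draw's (q, m, theta1, and LE
#' neighbor count), computes the weighted combination of that draw's
#' coefficient matrix, and draws counts from the Poisson data model. With
#' `processNoise = TRUE` (default) the forecast coefficients are drawn from
#' the truncated-normal process model around the bias-corrected weighted
#' combination — the complete posterior predictive, which is what calibrated
#' interval coverage requires; with `FALSE` the weighted combination is
#' plugged in directly, giving narrower intervals that reflect parameter and
#' count uncertainty only. Returns the draws with per-site predictive means
#' and central 95% interval endpoints (linear-interpolation empirical
#' quantiles).
#'
#' @param fit an [HBAPosterior-class].
#' @param cache the [DistanceCache-class] used for fitting, built with the
#'   forecast target among its `targetSteps`.
#' @param factorization the [NMFFactorization-class] used for fitting.
#' @param target index (or name) of the target among the cache's targets.
#' @param seed integer RNG seed for the predictive draws.
#' @param processNoise include the truncated-normal process layer in the
#'   predictive (default TRUE).
#' @return a [ForecastResult-class].
#' @export
hbaForecast <- function(fit, cache, factorization, target = 1L, seed = 1L,
                        processNoise = TRUE) {
    set.seed(seed)
    if (is.character(target)) target <- match(target, cache@targets)
    if (is.na(target) || length(cache@targetD[[1L]]) == 0L)
        stop("cache holds no distances for the requested forecast target")
    if (length(fit@pool) != length(cache@pool) ||
        any(fit@pool != cache@pool))
        cache <- subsetCachePool(cache, match(fit@pool, cache@pool))
    Psi <- basisMatrix(factorization)
    bOff <- offsetVector(factorization)
    nKeep <- length(fit@q)
    sampled <- dim(fit@B)[3L] == nKeep
    useLE <- length(fit@leK) > 0L
    draws <- matrix(0L, nrow(Psi), nKeep)
    for (l in seq_len(nKeep)) {
        w <- kernelWeights(target, cache, fit@q[l], fit@m[l], fit@theta1[l],
                           excludeSelf = FALSE,
                           le = if (useLE) fit@leK[l] else NULL)
        Bl <- if (sampled) fit@B[, , l] else fit@B[, , 1L]
        beta <- drop(Bl %*% w)
        if (processNoise) {
            s2 <- fit@sigma2eta[l]
            beta <- rtnorm0(length(beta),
                            tnProcessMean(beta, s2, fit@hyper@eps), s2)
        }
        lam <- Psi %*% beta + bOff
        draws[, l] <- rpois(nrow(Psi), lam)
    }
    new("ForecastResult", draws = draws, mean = rowMeans(draws),
        lower = apply(draws, 1L, quantile, probs = 0.025, names = FALSE),
        upper = apply(draws, 1L, quantile, probs = 0.975, names = FALSE),
        target = if (length(cache@targets)) cache@targets[target] else
            as.character(target),
        model = "HBA")
}
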