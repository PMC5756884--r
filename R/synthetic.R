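# Synthetic scenarios with known analog structure: a low-dimensional latent
# dynamical system observed as (i) a high-dimensional noisy forcing field and
# (ii) a sparse count field driven by the latent state at a lagged anchor
# step, plus a generator drawing directly from the analog process equations
# for parameter-recovery experiments.

#' Construct a synthetic scenario
#'
#' @param system `"lorenz"` (chaotic, the classic analog testbed) or
#'   `"quasiperiodic"` (two incommensurate frequencies; guarantees near-exact
#'   analogs for sharp end-to-end tests).
#' @param nSitesY,nSitesX response / forcing site counts.
#' @param nPeriods number of response periods.
#' @param stepsPerPeriod forcing steps per period (12 = monthly).
#' @param spinupSteps steps before the first period anchor (must be at least
#'   the deepest embedding minus one; default 72).
#' @param tau forecast lead in forcing steps.
#' @param anchorMonth anchor sub-period.
#' @param noiseSD forcing noise s.d. relative to unit-variance latent states.
#' @param intensityScale multiplier on count intensities.
#' @param zeroInflation extra-zero probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(system = c("lorenz", "quasiperiodic"),
                              nSitesY = 100L, nSitesX = 200L, nPeriods = 40L,
                              stepsPerPeriod = 12L, spinupSteps = 72L,
                              tau = 12L, anchorMonth = 5L, noiseSD = 0.2,
                              intensityScale = 6, zeroInflation = 0,
                              seed = 1L) {
    system <- match.arg(system)
    new("SyntheticScenario", system = system, nSitesY = as.integer(nSitesY),
        nSitesX = as.integer(nSitesX), nPeriods = as.integer(nPeriods),
        stepsPerPeriod = as.integer(stepsPerPeriod),
        spinupSteps = as.integer(spinupSteps), tau = as.integer(tau),
        anchorMonth = as.integer(anchorMonth), noiseSD = noiseSD,
        intensityScale = intensityScale, zeroInflation = zeroInflation,
        seed = as.integer(seed))
}

# total forcing steps: spinup + anchors for all periods plus one target year
scenarioSteps <- function(sc) {
    sc@spinupSteps + sc@stepsPerPeriod * (sc@nPeriods + 1L)
}

# latent trajectory, 3 x nSteps, standardized per coordinate.
# Lorenz-63 is integrated at dt = 0.02 and subsampled so consecutive "months"
# are close enough on the attractor that deep embeddings trace its loops.
latentTrajectory <- function(sc) {
    n <- scenarioSteps(sc)
    if (sc@system == "lorenz") {
        lorenz <- function(t, y, p) {
            list(c(p[1] * (y[2] - y[1]),
                   y[1] * (p[2] - y[3]) - y[2],
                   y[1] * y[2] - p[3] * y[3]))
        }
        thin <- 5L
        times <- seq(0, by = 0.02, length.out = 500L + n * thin)
        z <- deSolve::ode(c(1, 1, 20), times, lorenz, c(10, 28, 8 / 3),
                          method = "rk4")[, -1L]
        z <- t(z[500L + thin * seq_len(n), ])
    } else {
        s <- seq_len(n)
        # periods of 37 and 37*phi months: recurrent but never annual.
        # The orbit is deliberately asymmetric (harmonic distortion, unequal
        # axes): a pure circular torus is rotation-symmetric, and a rotation-
        # invariant shape distance could then match windows of any phase.
        p1 <- 37; p2 <- 37 * (1 + sqrt(5)) / 2
        ph1 <- 2 * pi * s / p1; ph2 <- 2 * pi * s / p2
        z <- rbind(sin(ph1) + 0.45 * sin(2 * ph1),
                   0.7 * cos(ph1) + 0.25 * cos(3 * ph1),
                   sin(ph2) + 0.35 * cos(2 * ph2))
    }
    (z - rowMeans(z)) / apply(z, 1L, sd)
}

# anchor forcing step of response period i (1-based), before the tau shift
scenarioAnchor <- function(sc, i) {
    sc@spinupSteps + sc@stepsPerPeriod * (i - 1L) + sc@anchorMonth
}

# month labels so that period i's anchor month falls in year = i
scenarioLabels <- function(sc) {
    firstIdx <- 12L - sc@spinupSteps   # step 1's absolute month index
    idx <- firstIdx + seq_len(scenarioSteps(sc)) - 1L
    data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

#' Simulate the forcing field of a scenario
#'
#' `x_t' = L z_t' + noise`, with loadings `L` (sites x 3) drawn once from the
#' scenario seed, and year/month labels attached so that period i's anchor
#' month falls in year i.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param loadings optional fixed loading matrix (sites x 3); default drawn
#'   from the scenario seed.
#' @return a [ForcingSeries-class].
#' @export
simulateForcing <- function(scenario, loadings = NULL) {
    set.seed(scenario@seed)
    z <- latentTrajectory(scenario)
    L <- if (is.null(loadings)) matrix(rnorm(scenario@nSitesX * 3L),
                                       scenario@nSitesX, 3L)
         else loadings
    x <- L %*% z +
        matrix(rnorm(length(z) / 3 * scenario@nSitesX, 0, scenario@noiseSD),
               scenario@nSitesX, ncol(z))
    lab <- scenarioLabels(scenario)
    coords <- data.frame(lon = seq(120, 290, length.out = scenario@nSitesX),
                         lat = rep(0, scenario@nSitesX))
    ForcingSeries(x, coords, lab$year, lab$month)
}

#' Simulate the count field of a scenario
#'
#' Per-site Poisson intensities are a softplus link of a site-specific linear
#' map of the latent state at each period's anchored step minus the lead
#' `tau` — exactly the step an analog model aligned with the same `tau` would
#' use — so true analogs exist by construction. Optional independent
#' zero-inflation thins counts to zero.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param includeTarget also return the held-out target period
#'   (`nPeriods + 1`) so forecasts can be scored against truth.
#' @return a [SpaceTimeCounts-class] with `nPeriods` (+1 when
#'   `includeTarget`) columns; the true intensities are stored in
#'   `metadata(x)$lambda`.
#' @export
simulateCounts <- function(scenario, includeTarget = FALSE) {
    set.seed(scenario@seed + 1L)
    z <- latentTrajectory(scenario)
    ny <- scenario@nSitesY
    U <- matrix(rnorm(ny * 3L), ny, 3L)
    u0 <- rnorm(ny, -0.5, 0.7)
    nT <- scenario@nPeriods + as.integer(includeTarget)
    lam <- matrix(0, ny, nT)
    for (i in seq_len(nT)) {
        s <- scenarioAnchor(scenario, i) - scenario@tau
        eta <- drop(U %*% z[, s]) + u0
        lam[, i] <- scenario@intensityScale * log1p(exp(eta))
    }
    y <- matrix(rpois(ny * nT, lam), ny, nT)
    if (scenario@zeroInflation > 0)
        y[matrix(runif(ny * nT) < scenario@zeroInflation, ny, nT)] <- 0L
    coords <- data.frame(lon = runif(ny, -115, -96), lat = runif(ny, 43, 54))
    out <- SpaceTimeCounts(y, coords, seq_len(nT))
    metadata(out)$lambda <- lam
    out
}

#' Draw a full dataset from the analog process equations themselves
#'
#' Simulates forcing coefficient series (a rescaled chaotic latent
#' trajectory), builds embedding distances at the true depth, then draws the
#' coefficient matrix from the truncated-normal process model with the true
#' weights: a sequential pass over periods followed by Gibbs-style sweeps of
#' the process conditionals with the full symmetric neighborhoods, so the
#' realised field is a draw from the same conditional structure the model
#' fits. Each period's location is the bias-corrected, eps-floored weighted
#' combination of its m* nearest analogs' coefficients; counts come from the
#' Poisson data model through a fixed sparse nonnegative basis scaled so
#' site intensities are O(10). The latent trajectory is rescaled so typical
#' nearest-analog distances are commensurate with the kernel prior scale,
#' keeping both the depth and the kernel parameter identifiable. Ground
#' truth is returned for parameter-recovery experiments.
#'
#' @param qStar,mStar,theta1Star,sigma2Star true embedding depth,
#'   neighborhood size, kernel parameter and process variance.
#' @param seed integer seed.
#' @param nPeriods,nBasis,nAlpha,nSitesY problem dimensions.
#' @param eps process-mean floor.
#' @param gibbsSweeps conditional-resampling sweeps after the sequential
#'   pass (default 50).
#' @param distScale latent-trajectory scaling: the median nearest-analog
#'   Procrustes distance at the true depth is set to
#'   `distScale * sqrt(theta1Star)`.
#' @return list with `counts` ([SpaceTimeCounts-class], `nPeriods` columns
#'   plus the held-out target in `$holdout`), `coeffs`
#'   ([ForcingCoefficients-class]), `alignment` (named anchor-step vector),
#'   `targetStep`, `B` (true coefficients incl. target column), `basis`,
#'   `truth` (the generating parameters).
#' @export
processModelFixture <- function(qStar = 45L, mStar = 3L, theta1Star = 0.1,
                                sigma2Star = 0.02, seed = 1L,
                                nPeriods = 40L, nBasis = 5L, nAlpha = 3L,
                                nSitesY = 100L, eps = 1e-6,
                                gibbsSweeps = 50L, distScale = 4) {
    set.seed(seed)
    sc <- syntheticScenario("lorenz", nSitesY = nSitesY,
                            nPeriods = nPeriods, seed = seed)
    z <- latentTrajectory(sc)
    alpha <- if (nAlpha <= 3L) z[seq_len(nAlpha), , drop = FALSE]
             else rbind(z, matrix(rnorm((nAlpha - 3L) * ncol(z), 0, 1),
                                  nAlpha - 3L, ncol(z)))
    anchors <- vapply(seq_len(nPeriods + 1L), function(i)
        scenarioAnchor(sc, i) - sc@tau, integer(1))
    # scale so the median nearest-analog distance at qStar is
    # distScale * sqrt(theta1*): near analogs then get near-unit kernel
    # values while the far neighborhood decays sharply, keeping both the
    # depth and the kernel parameter identifiable
    emb <- lapply(anchors[seq_len(nPeriods)], function(s) {
        e <- alpha[, seq.int(s, by = -1L, length.out = qStar), drop = FALSE]
        e - rowMeans(e)
    })
    nn <- vapply(seq_len(nPeriods), function(i) {
        min(vapply(seq_len(nPeriods)[-i], function(j)
            centeredProcrustes(emb[[i]], emb[[j]], sum(emb[[i]]^2),
                               sum(emb[[j]]^2), 1), numeric(1)))
    }, numeric(1))
    alpha <- alpha * distScale * sqrt(theta1Star) / stats::median(nn)
    names(anchors) <- seq_len(nPeriods + 1L)
    coeffs <- new("ForcingCoefficients", coef = alpha, method = "EOF",
                  basis = matrix(0, 0, 0), varianceExplained = numeric(0),
                  leNeighbors = NA_integer_,
                  stepYear = scenarioLabels(sc)$year,
                  stepMonth = scenarioLabels(sc)$month)
    # draw B from the process model with the true weights: sequential pass,
    # then Gibbs sweeps of the symmetric-neighborhood conditionals
    dAll <- procrustesDistanceMatrix(alpha, anchors, qStar, 1)$dist
    trueW <- function(t, candidates) {
        mEff <- min(mStar, length(candidates))
        o <- candidates[order(dAll[t, candidates])][seq_len(mEff)]
        d <- dAll[t, o]
        wt <- exp(-(d^2 - d[1L]^2) / (2 * theta1Star))
        list(idx = o, w = wt / sum(wt))
    }
    B <- matrix(0, nBasis, nPeriods + 1L)
    B[, 1L] <- rtnorm0(nBasis, 1.5, sigma2Star)
    for (t in seq.int(2L, nPeriods)) {
        tw <- trueW(t, seq_len(t - 1L))
        a <- drop(B[, tw$idx, drop = FALSE] %*% tw$w)
        B[, t] <- rtnorm0(nBasis, tnProcessMean(a, sigma2Star, eps),
                          sigma2Star)
    }
    for (sweep in seq_len(gibbsSweeps)) for (t in seq_len(nPeriods)) {
        tw <- trueW(t, seq_len(nPeriods)[-t])
        a <- drop(B[, tw$idx, drop = FALSE] %*% tw$w)
        B[, t] <- rtnorm0(nBasis, tnProcessMean(a, sigma2Star, eps),
                          sigma2Star)
    }
    tw <- trueW(nPeriods + 1L, seq_len(nPeriods))
    a <- drop(B[, tw$idx, drop = FALSE] %*% tw$w)
    B[, nPeriods + 1L] <- rtnorm0(nBasis,
                                  tnProcessMean(a, sigma2Star, eps),
                                  sigma2Star)
    # sparse nonnegative basis scaled so site intensities are O(10):
    # counts then carry real information and 95% predictive intervals are
    # not dominated by integer discreteness
    Psi <- 8 * matrix(rgamma(nSitesY * nBasis, 2, 2), nSitesY, nBasis)
    Psi[matrix(runif(nSitesY * nBasis) < 0.5, nSitesY, nBasis)] <- 0
    lam <- Psi %*% B
    y <- matrix(rpois(length(lam), lam), nSitesY, nPeriods + 1L)
    counts <- SpaceTimeCounts(y[, seq_len(nPeriods), drop = FALSE],
                              data.frame(lon = runif(nSitesY, -115, -96),
                                         lat = runif(nSitesY, 43, 54)),
                              seq_len(nPeriods))
    list(counts = counts, holdout = y[, nPeriods + 1L], coeffs = coeffs,
         alignment = anchors[seq_len(nPeriods)],
         targetStep = anchors[[nPeriods + 1L]],
         B = B, basis = Psi, lambdaTarget = drop(lam[, nPeriods + 1L]),
         truth = list(q = qStar, m = mStar, theta1 = theta1Star,
                      sigma2 = sigma2Star, eps = eps, seed = seed))
}
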