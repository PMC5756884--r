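# The comparison Poisson space-time (PST) model: log-Gaussian intensities on
# a fixed spatial basis derived from kernel PCA, latent coefficients evolving
# as a reduced-rank VAR, conjugate Gibbs updates where available and
# elementwise Metropolis-Hastings for the log intensities.

#' Kernel principal component coefficients
#'
#' Treats time points (columns) as observations, double-centers the kernel
#' matrix, and returns the leading score series (scores are eigenvectors
#' scaled by the square root of their eigenvalues, so a linear kernel
#' reproduces ordinary PCA scores). Also returns a linear pre-image basis
#' `Xc V diag(1/sqrt(lambda))` mapping scores back to (centered) field space,
#' which the PST model uses as its fixed spatial basis. The Gaussian
#' bandwidth defaults to the median pairwise distance (median heuristic).
#'
#' @param x field matrix, sites x time points (e.g. `log1p` counts).
#' @param nComponents number of components.
#' @param kernel `"gaussian"` or `"linear"`.
#' @param bandwidth Gaussian kernel bandwidth; `NULL` = median heuristic.
#' @return a [ForcingCoefficients-class] with method `"KPCA"`; `coef` holds
#'   the score series and `basis` the pre-image basis.
#' @export
kpcaCoefficients <- function(x, nComponents, kernel = c("gaussian", "linear"),
                             bandwidth = NULL) {
    kernel <- match.arg(kernel)
    x <- as.matrix(x)
    n <- ncol(x)
    nComponents <- as.integer(nComponents)
    if (kernel == "gaussian") {
        d <- as.matrix(stats::dist(t(x)))
        if (is.null(bandwidth)) {
            bandwidth <- stats::median(d[upper.tri(d)])
            # degenerate field (all points identical): any bandwidth gives
            # the same constant kernel; the rank check below reports it
            if (bandwidth <= 0) bandwidth <- 1
        }
        stopifnot(bandwidth > 0)
        K <- exp(-d^2 / (2 * bandwidth^2))
    } else {
        K <- crossprod(x)
    }
    H <- diag(n) - matrix(1 / n, n, n)
    Kc <- H %*% K %*% H
    Kc <- (Kc + t(Kc)) / 2
    eg <- eigen(Kc, symmetric = TRUE)
    tol <- 1e-10 * max(eg$values, 1)
    if (nComponents > sum(eg$values > tol))
        stop("kernel matrix rank below nComponents")
    lam <- eg$values[seq_len(nComponents)]
    v <- eg$vectors[, seq_len(nComponents), drop = FALSE]
    flip <- apply(v, 2L, function(u) sign(u[which.max(abs(u))]))
    v <- v * rep(flip, each = n)
    scores <- t(v) * sqrt(lam)            # nComponents x n
    xc <- x - rowMeans(x)
    preimage <- xc %*% v %*% diag(1 / sqrt(lam), nComponents)
    new("ForcingCoefficients", coef = scores, method = "KPCA",
        basis = preimage, varianceExplained = numeric(0),
        leNeighbors = NA_integer_, stepYear = integer(0),
        stepMonth = integer(0))
}

#' Fit the Poisson space-time baseline model
#'
#' The PST model: counts are Poisson with log intensity
#' `nu_t ~ N(Z c + Psi alpha_t, sigma2eps I)` where `Z` holds an intercept
#' and standardized longitude/latitude, `Psi` is a fixed spatial basis
#' (typically the kernel-PCA pre-image basis of the log1p counts), and the
#' latent coefficients follow a first-order VAR
#' `alpha_t ~ N(H alpha_{t-1}, SigmaGamma)`. Sampling: elementwise
#' Metropolis-Hastings for the log intensities (adaptive global step during
#' burn-in), conjugate Gaussian updates for `alpha_t`, `c` and `vec(H)`,
#' inverse-Wishart for `SigmaGamma` and inverse-gamma for `sigma2eps`.
#'
#' @param counts a [SpaceTimeCounts-class] or count matrix.
#' @param basis fixed spatial basis, sites x components (see
#'   [kpcaCoefficients()]).
#' @param coords data.frame with `lon`, `lat`; taken from `counts` when it is
#'   a [SpaceTimeCounts-class].
#' @param nIter,burnIn iteration counts.
#' @param seed integer RNG seed.
#' @return a [PSTPosterior-class].
#' @export
pstFit <- function(counts, basis, coords = NULL, nIter = 3000L,
                   burnIn = 500L, seed = 1L) {
    set.seed(seed)
    if (is(counts, "SpaceTimeCounts")) {
        if (is.null(coords)) coords <- siteCoords(counts)
        Y <- counts(counts)
    } else Y <- as.matrix(counts)
    ny <- nrow(Y); Tn <- ncol(Y)
    stopifnot(Tn >= 3L)
    Psi <- as.matrix(basis)
    nc <- ncol(Psi)
    Z <- if (is.null(coords)) matrix(1, ny, 1L)
         else cbind(1, scale(coords$lon)[, 1L], scale(coords$lat)[, 1L])
    p <- ncol(Z)

    # init
    nu <- log(Y + 0.5)
    cVec <- qr.solve(Z, rowMeans(nu))
    alpha <- crossprod(Psi, nu - drop(Z %*% cVec)) /
        colSums(Psi^2)                      # rough projection
    H <- diag(0.5, nc)
    SigG <- diag(0.1, nc)
    s2e <- 0.1
    stepNu <- 0.3
    accNu <- totNu <- 0
    priorC <- 100; priorH <- 100
    nu0 <- nc + 2; S0 <- diag(0.1, nc)
    ae <- be <- 0.01

    nKeep <- nIter - burnIn
    out <- list(muCoef = matrix(0, p, nKeep),
                alpha = array(0, c(nc, Tn, nKeep)),
                H = array(0, c(nc, nc, nKeep)),
                SigG = array(0, c(nc, nc, nKeep)),
                s2e = numeric(nKeep))

    PtP <- crossprod(Psi)
    for (it in seq_len(nIter)) {
        mean_nu <- drop(Z %*% cVec) + Psi %*% alpha
        ## nu: elementwise MH (independent given alpha) ------------------
        nuP <- nu + matrix(rnorm(ny * Tn, 0, stepNu), ny, Tn)
        logR <- (Y * nuP - exp(nuP)) - (Y * nu - exp(nu)) +
            (-(nuP - mean_nu)^2 + (nu - mean_nu)^2) / (2 * s2e)
        take <- matrix(log(runif(ny * Tn)), ny, Tn) < logR
        nu[take] <- nuP[take]
        accNu <- accNu + sum(take); totNu <- totNu + length(take)
        if (it <= burnIn && it %% 50L == 0L) {
            r <- accNu / totNu
            stepNu <- stepNu * exp(0.3 * (r > 0.5) - 0.3 * (r < 0.2))
            accNu <- totNu <- 0
        }
        ## alpha_t: conjugate Gaussian -----------------------------------
        resid <- nu - drop(Z %*% cVec)
        SigGi <- solve(SigG)
        HtSiH <- crossprod(H, SigGi %*% H)
        for (t in seq_len(Tn)) {
            prec <- PtP / s2e
            rhs <- crossprod(Psi, resid[, t]) / s2e
            if (t == 1L) {
                prec <- prec + diag(1 / 10, nc)
            } else {
                prec <- prec + SigGi
                rhs <- rhs + SigGi %*% (H %*% alpha[, t - 1L])
            }
            if (t < Tn) {
                prec <- prec + HtSiH
                rhs <- rhs + crossprod(H, SigGi %*% alpha[, t + 1L])
            }
            ch <- chol(prec)
            mn <- backsolve(ch, forwardsolve(t(ch), rhs))
            alpha[, t] <- mn + backsolve(ch, rnorm(nc))
        }
        ## H: conjugate on vec(H) ----------------------------------------
        A0 <- alpha[, -Tn, drop = FALSE]
        A1 <- alpha[, -1L, drop = FALSE]
        Sxx <- tcrossprod(A0)
        prec <- kronecker(Sxx, SigGi) + diag(1 / priorH, nc * nc)
        rhs <- as.vector(SigGi %*% A1 %*% t(A0))
        ch <- chol(prec)
        vH <- backsolve(ch, forwardsolve(t(ch), rhs)) +
            backsolve(ch, rnorm(nc * nc))
        H <- matrix(vH, nc, nc)
        ## SigmaGamma: inverse-Wishart ------------------------------------
        E <- A1 - H %*% A0
        Sc <- S0 + tcrossprod(E)
        SigG <- solve(rWishart(1L, nu0 + Tn - 1L, solve(Sc))[, , 1L])
        ## c: conjugate regression ----------------------------------------
        r2 <- nu - Psi %*% alpha
        prec <- Tn * crossprod(Z) / s2e + diag(1 / priorC, p)
        rhs <- crossprod(Z, rowSums(r2)) / s2e
        ch <- chol(prec)
        cVec <- drop(backsolve(ch, forwardsolve(t(ch), rhs)) +
                     backsolve(ch, rnorm(p)))
        ## sigma2eps ------------------------------------------------------
        rr <- r2 - drop(Z %*% cVec)
        s2e <- 1 / rgamma(1L, ae + ny * Tn / 2, be + sum(rr^2) / 2)
        if (!is.finite(s2e) || s2e <= 0)
            stop("divergent chain: non-finite observation variance")
        ## retain ---------------------------------------------------------
        if (it > burnIn) {
            k <- it - burnIn
            out$muCoef[, k] <- cVec
            out$alpha[, , k] <- alpha
            out$H[, , k] <- H
            out$SigG[, , k] <- SigG
            out$s2e[k] <- s2e
        }
    }
    new("PSTPosterior", muCoef = out$muCoef, alpha = out$alpha, H = out$H,
        SigmaGamma = out$SigG, sigma2eps = out$s2e, basis = Psi, Z = Z,
        acceptRates = c(nu = accNu / max(totNu, 1)), seed = as.integer(seed))
}

#' One-step-ahead forecast from the Poisson space-time baseline
#'
#' Per retained draw: `alpha_{T+1} ~ N(H alpha_T, SigmaGamma)`, the log
#' intensity through the Gaussian observation layer, and counts from the
#' Poisson data model. Output schema matches [hbaForecast()].
#'
#' @param fit a [PSTPosterior-class].
#' @param seed integer RNG seed.
#' @param target character label for the forecast period.
#' @return a [ForecastResult-class].
#' @export
pstForecast <- function(fit, seed = 1L, target = "T+1") {
    set.seed(seed)
    nKeep <- length(fit@sigma2eps)
    nc <- dim(fit@alpha)[1L]
    Tn <- dim(fit@alpha)[2L]
    ny <- nrow(fit@basis)
    # eigen square root tolerates singular (even zero) innovation covariance
    sqrtPSD <- function(S) {
        e <- eigen(S, symmetric = TRUE)
        e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    }
    draws <- matrix(0L, ny, nKeep)
    for (l in seq_len(nKeep)) {
        aNew <- drop(fit@H[, , l] %*% fit@alpha[, Tn, l]) +
            drop(sqrtPSD(fit@SigmaGamma[, , l]) %*% rnorm(nc))
        nuNew <- drop(fit@Z %*% fit@muCoef[, l]) +
            drop(fit@basis %*% aNew) +
            rnorm(ny, 0, sqrt(fit@sigma2eps[l]))
        draws[, l] <- rpois(ny, exp(pmin(nuNew, 30)))
    }
    new("ForecastResult", draws = draws, mean = rowMeans(draws),
        lower = apply(draws, 1L, quantile, probs = 0.025, names = FALSE),
        upper = apply(draws, 1L, quantile, probs = 0.975, names = FALSE),
        target = target, model = "PST")
}
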