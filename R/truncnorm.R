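# Left-truncated (at zero) normal utilities: mean map, its inverse (the bias
# correction applied to the analog process mean), densities and sampling.

# inverse Mills ratio phi(z)/Phi(z), stable for very negative z via log scale
millsRatio <- function(z) {
    exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
}

#' Mean of a normal distribution left-truncated at zero
#'
#' For X ~ N(mu, sigma2) conditioned on X >= 0, returns
#' `E(X) = mu + sigma * phi(mu/sigma) / Phi(mu/sigma)`. The mean of the
#' truncated distribution always exceeds `max(0, mu)`: truncation at zero
#' biases the location upward, most strongly when `mu` is near or below zero.
#'
#' @param mu location parameter (vectorised).
#' @param sigma2 positive variance of the untruncated normal.
#' @return the truncated-normal mean, same length as `mu`.
#' @seealso [biasCorrectH()] for the inverse map.
#' @examples
#' tnMean(0, 1)            # half-normal mean sqrt(2/pi)
#' tnMean(10, 1)           # ~10: truncation negligible far from zero
#' @export
tnMean <- function(mu, sigma2) {
    stopifnot(sigma2 > 0)
    s <- sqrt(sigma2)
    s * tnMeanScaled(mu / s)
}

# scaled mean map psi(z) = z + mills(z); the direct form cancels
# catastrophically for z << 0, so the deep tail uses the asymptotic series
# psi(z) = 1/u - 2/u^3 + 10/u^5 + O(u^-7), u = -z (both branches accurate to
# ~1e-11 at the z = -30 switch point)
tnMeanScaled <- function(z) {
    out <- z + millsRatio(z)
    deep <- z < -30
    if (any(deep)) {
        u <- -z[deep]
        out[deep] <- 1 / u - 2 / u^3 + 10 / u^5
    }
    out
}

# d/dz of psi; always in (0, 1]; used by the Newton solver
tnMeanScaledDeriv <- function(z) {
    m <- millsRatio(z)
    out <- pmax(1 - z * m - m * m, 1e-14)
    deep <- z < -30
    if (any(deep)) {
        u <- -z[deep]
        out[deep] <- 1 / u^2 - 6 / u^4 + 50 / u^6
    }
    out
}

# Bracketed Newton/bisection inverse of psi(z) = z + mills(z): solves
# psi(z) = r for r > 0. psi is strictly increasing with psi(z) ~ -1/z as
# z -> -Inf and ~ z as z -> Inf, giving the analytic brackets
# [-1/r, r] (small r) and [r - 0.8, r] (r >= psi(0) = sqrt(2/pi)).
tnMeanScaledInverseSlow <- function(r, tol = 1e-12, maxIter = 200L) {
    stopifnot(all(r > 0))
    psi <- tnMeanScaled
    lo <- ifelse(r >= 0.8, r - 0.8, -1 / r)
    hi <- r
    z <- (lo + hi) / 2
    for (it in seq_len(maxIter)) {
        f <- psi(z) - r
        if (all(abs(f) < tol)) break
        below <- f < 0
        lo[below] <- z[below]
        hi[!below] <- z[!below]
        z <- z - f / tnMeanScaledDeriv(z)
        out <- z <= lo | z >= hi
        z[out] <- (lo[out] + hi[out]) / 2
    }
    z
}

# lazily built monotone spline of z = psi^{-1}(exp(.)) on a log grid,
# used as the Newton starting point for the fast path
.psiInvCache <- new.env(parent = emptyenv())

psiInvInit <- function(r) {
    if (is.null(.psiInvCache$fun)) {
        lr <- seq(log(1e-8), log(1e4), length.out = 4096L)
        .psiInvCache$fun <- stats::splinefun(
            lr, tnMeanScaledInverseSlow(exp(lr)), method = "monoH.FC")
    }
    z <- numeric(length(r))
    mid <- r >= 1e-8 & r <= 1e4
    z[mid] <- .psiInvCache$fun(log(r[mid]))
    z[r < 1e-8] <- -1 / r[r < 1e-8] + 2 * r[r < 1e-8]
    z[r > 1e4] <- r[r > 1e4]
    z
}

# fast vectorised inverse: spline start + two Newton polish steps (the start
# is accurate to ~1e-7, so two quadratic steps reach ~1e-12 in r-units)
tnMeanScaledInverse <- function(r, tol = 1e-12) {
    if (any(r <= 0)) stop("r must be positive")
    z <- psiInvInit(r)
    for (it in 1:3) {
        m <- millsRatio(z)
        deep <- z < -30
        f <- z + m
        dpsi <- pmax(1 - z * m - m * m, 1e-14)
        if (any(deep)) {
            u <- -z[deep]
            f[deep] <- 1 / u - 2 / u^3 + 10 / u^5
            dpsi[deep] <- 1 / u^2 - 6 / u^4 + 50 / u^6
        }
        f <- f - r
        if (it > 1L && all(abs(f) < tol)) break
        z <- z - f / dpsi
    }
    z
}

#' Bias correction for the left-truncated normal mean
#'
#' Returns the location `mu*` such that a N(mu*, sigma2) distribution
#' truncated to `[0, Inf)` has mean exactly `a`; i.e. the inverse of
#' [tnMean()] in its first argument. Used to de-bias the analog process
#' model: without it, the truncated-normal process mean would systematically
#' exceed the weighted-analog prediction, most severely for coefficients near
#' zero. As `a -> 0+` the corrected location diverges to `-Inf`, which is why
#' the process model floors the result at a small `eps`.
#'
#' @param a positive target mean (vectorised); values `<= 0` are an error —
#'   callers must apply their floor first.
#' @param sigma2 positive variance of the untruncated normal.
#' @param tol absolute tolerance of the root (default `1e-10`).
#' @return the location `mu*`, same length as `a`.
#' @examples
#' biasCorrectH(sqrt(2 / pi), 1)          # 0: inverts the half-normal mean
#' tnMean(biasCorrectH(10, 1), 1)         # 10: definitional round trip
#' @export
biasCorrectH <- function(a, sigma2, tol = 1e-10) {
    stopifnot(sigma2 > 0)
    if (any(a <= 0))
        stop("'a' must be positive; apply the eps floor before calling")
    s <- sqrt(sigma2)
    s * tnMeanScaledInverse(a / s, tol = tol / s)
}

# Process-model mean: elementwise max(h(a, sigma2), eps), with mean = eps
# wherever a <= aFloor = tnMean(eps, sigma2) (h(a) <= eps there, including the
# degenerate a <= 0 case where h is undefined).
tnProcessMean <- function(a, sigma2, eps) {
    mu <- rep.int(eps, length(a))
    aFloor <- tnMean(eps, sigma2)
    idx <- which(a > aFloor)
    if (length(idx))
        mu[idx] <- biasCorrectH(a[idx], sigma2)
    dim(mu) <- dim(a)
    mu
}

# log density of N(mu, sigma2) truncated to [0, Inf), elementwise
tnLogDensity <- function(x, mu, sigma2) {
    s <- sqrt(sigma2)
    ifelse(x < 0, -Inf,
           dnorm(x, mu, s, log = TRUE) - pnorm(mu / s, log.p = TRUE))
}

# draw from N(mu, sigma2) truncated to [0, Inf) by inverse-CDF, vectorised
rtnorm0 <- function(n, mu, sigma2) {
    s <- sqrt(sigma2)
    p0 <- pnorm(-mu / s)
    u <- p0 + runif(n) * (1 - p0)
    # guard u == 1 rounding for mu/s << 0
    mu + s * qnorm(pmin(u, 1 - 1e-16))
}
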