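# kernel PCA scores and the Poisson space-time baseline

test_that("linear-kernel KPCA reproduces PCA scores", {
    set.seed(1)
    x <- matrix(rnorm(8 * 12), 8, 12)
    kp <- kpcaCoefficients(x, 3, kernel = "linear")
    pc <- prcomp(t(x), center = TRUE)
    expect_equal(abs(unname(coefMatrix(kp))),
                 abs(unname(t(pc$x[, 1:3]))), tolerance = 1e-8)
    # pre-image basis reconstructs the centered field from the scores
    rec <- basisMatrix(kp) %*% coefMatrix(kp)
    full <- kpcaCoefficients(x, 8, kernel = "linear")
    expect_equal(basisMatrix(full) %*% coefMatrix(full), x - rowMeans(x),
                 tolerance = 1e-8)
    expect_lt(mean((rec - (x - rowMeans(x)))^2), mean(x^2))
})

test_that("Gaussian-kernel matrix is double-centered; duplicates share scores", {
    set.seed(2)
    x <- matrix(rnorm(5 * 9), 5, 9)
    x[, 9] <- x[, 1]
    d <- as.matrix(dist(t(x)))
    h <- median(d[upper.tri(d)])
    K <- exp(-d^2 / (2 * h^2))
    H <- diag(9) - matrix(1 / 9, 9, 9)
    Kc <- H %*% K %*% H
    expect_lt(max(abs(rowSums(Kc))), 1e-8)
    kp <- kpcaCoefficients(x, 3)
    expect_equal(coefMatrix(kp)[, 1], coefMatrix(kp)[, 9], tolerance = 1e-8)
    expect_error(kpcaCoefficients(matrix(1, 4, 6), 3), "rank")
})

test_that("the VAR transition matrix is recovered from simulated data", {
    set.seed(3)
    ny <- 100; Tn <- 60; nc <- 3
    Psi <- qr.Q(qr(matrix(rnorm(ny * nc), ny, nc)))
    H <- diag(0.5, nc)
    alpha <- matrix(0, nc, Tn)
    for (t in 2:Tn) alpha[, t] <- H %*% alpha[, t - 1] + rnorm(nc, 0, 0.4)
    coords <- data.frame(lon = runif(ny), lat = runif(ny))
    Z <- cbind(1, scale(coords$lon)[, 1], scale(coords$lat)[, 1])
    cTrue <- c(1.2, 0.1, -0.1)
    nu <- drop(Z %*% cTrue) + 3 * Psi %*% alpha +
        matrix(rnorm(ny * Tn, 0, 0.05), ny, Tn)
    y <- matrix(rpois(ny * Tn, exp(pmin(nu, 10))), ny, Tn)
    fit <- pstFit(y, 3 * Psi, coords, nIter = 1500, burnIn = 400, seed = 9)
    hHat <- apply(fit@H, c(1, 2), mean)
    expect_true(all(abs(diag(hHat) - 0.5) < 0.15))
    expect_equal(dim(fit@alpha)[3], 1100L)
    # null case: independent latent states give |H| entries near zero
    # (longer series so the posterior s.e. of each entry is well below 0.2)
    Tn0 <- 200
    alpha0 <- matrix(rnorm(nc * Tn0, 0, 0.4), nc, Tn0)
    nu0 <- drop(Z %*% cTrue) + 3 * Psi %*% alpha0 +
        matrix(rnorm(ny * Tn0, 0, 0.05), ny, Tn0)
    y0 <- matrix(rpois(ny * Tn0, exp(pmin(nu0, 10))), ny, Tn0)
    fit0 <- pstFit(y0, 3 * Psi, coords, nIter = 1200, burnIn = 400,
                   seed = 10)
    expect_true(all(abs(apply(fit0@H, c(1, 2), mean)) < 0.2))
})

test_that("PST forecast has the shared schema and a verifiable mean", {
    set.seed(4)
    ny <- 3; nc <- 2; Tn <- 10
    fit <- new("PSTPosterior",
               muCoef = matrix(c(1, 0, 0), 3, 500),
               alpha = array(0.3, c(nc, Tn, 500)),
               H = array(diag(0.4, nc), c(nc, nc, 500)),
               SigmaGamma = array(diag(0.02, nc), c(nc, nc, 500)),
               sigma2eps = rep(0.01, 500),
               basis = matrix(c(1, 0.5, -0.5, 0.2, 0.1, 0.3), ny, nc),
               Z = cbind(rep(1, ny), 0, 0),
               acceptRates = c(nu = 0.4), seed = 1L)
    # fully degenerate dynamics: predictive mean collapses to exp(mu)
    fit0 <- fit
    fit0@H <- array(0, c(nc, nc, 500))
    fit0@SigmaGamma <- array(0, c(nc, nc, 500))
    fit0@sigma2eps <- rep(0, 500)
    fc0 <- pstForecast(fit0, seed = 5)
    expect_equal(fc0@mean, rep(exp(1), ny),
                 tolerance = 6 * sqrt(exp(1) / 500) / exp(1))
    fc <- pstForecast(fit, seed = 2)
    expect_s4_class(fc, "ForecastResult")
    expect_identical(fc@model, "PST")
    expect_true(all(fc@draws == round(fc@draws) & fc@draws >= 0))
    expect_true(all(fc@lower <= fc@upper))
    # direct simulation oracle for the predictive mean
    set.seed(99)
    nSim <- 2e5
    aNew <- 0.4 * 0.3 + rnorm(nSim, 0, sqrt(0.02))
    aNew2 <- 0.4 * 0.3 + rnorm(nSim, 0, sqrt(0.02))
    for (i in 1:ny) {
        nuI <- 1 + fit@basis[i, 1] * aNew + fit@basis[i, 2] * aNew2 +
            rnorm(nSim, 0, 0.1)
        oracle <- mean(exp(nuI))
        expect_equal(mean(fc@draws[i, ]), oracle,
                     tolerance = 6 * sd(exp(nuI)) / sqrt(500) / oracle + 0.02)
    }
})
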