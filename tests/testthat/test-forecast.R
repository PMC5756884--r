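# posterior-predictive analog forecasting

test_that("degenerate weights reduce the forecast to one period's intensity", {
    # target embedding duplicates pool period 2 exactly -> weight 1 there
    co <- tinyCoeffs(2)
    co@coef[, 101:115] <- co@coef[, 26:40]
    anchors <- setNames(c(25, 40, 60, 80, 100), 1:5)
    cache <- buildDistanceCache(co, anchors, qRange = 15,
                                targetSteps = c(tt = 115))
    set.seed(8)
    ny <- 30
    Psi <- matrix(rgamma(ny * 2, 3, 1), ny, 2)
    B <- matrix(runif(10, 0.5, 2), 2, 5)
    fact <- new("NMFFactorization", basis = Psi, coef = B,
                offset = rep(0, ny), lossTrace = c(1, .5), rank = 2L,
                init = "custom")
    nKeep <- 600L
    fit <- new("HBAPosterior", q = rep(15L, nKeep), m = rep(1L, nKeep),
               theta1 = rep(0.1, nKeep), sigma2eta = rep(0.01, nKeep),
               leK = integer(0), B = array(B, c(2, 5, 1)),
               logJoint = numeric(nKeep), acceptRates = c(q = .5),
               hyper = HBAHyperParams(qMin = 15L, qMax = 15L),
               pool = 1:5, seed = 1L)
    fc <- hbaForecast(fit, cache, fact, target = 1L, seed = 3,
                      processNoise = FALSE)
    lamStar <- drop(Psi %*% B[, 2])
    # predictive mean per site -> Poisson mean at the matched analog
    mcse <- sqrt(lamStar / nKeep)
    expect_true(all(abs(fc@mean - lamStar) < 5 * mcse + 0.05))
    # schema properties
    expect_true(all(fc@draws >= 0 & fc@draws == round(fc@draws)))
    expect_true(all(fc@lower <= fc@mean & fc@mean <= fc@upper))
})

test_that("forecast draws vary with the sampled parameters and seed", {
    s <- local({
        fx <- processModelFixture(seed = 5, nPeriods = 16, nSitesY = 20L,
                                  qStar = 9L, gibbsSweeps = 5L)
        hyper <- HBAHyperParams(qMin = 7L, qMax = 11L, mMin = 1L, mMax = 4L)
        cache <- buildDistanceCache(fx$coeffs, fx$alignment, 7:11, 1,
                                    c(target = fx$targetStep))
        fact <- new("NMFFactorization", basis = fx$basis,
                    coef = fx$B[, 1:16], offset = rep(0, nrow(fx$basis)),
                    lossTrace = c(1, .5), rank = 5L, init = "custom")
        fit <- hbaFit(fx$counts, fact, cache, hyper, 400, 100, seed = 2)
        list(fit = fit, cache = cache, fact = fact)
    })
    f1 <- hbaForecast(s$fit, s$cache, s$fact, 1L, seed = 1)
    f2 <- hbaForecast(s$fit, s$cache, s$fact, 1L, seed = 1)
    f3 <- hbaForecast(s$fit, s$cache, s$fact, 1L, seed = 2)
    expect_identical(f1@draws, f2@draws)
    expect_false(identical(f1@draws, f3@draws))
    expect_error(hbaForecast(s$fit,
                             buildDistanceCache(tinyCoeffs(1),
                                                setNames(c(50, 60), 1:2),
                                                7:11),
                             s$fact), "target")
})
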