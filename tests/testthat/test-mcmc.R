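# Metropolis-Hastings sampler mechanics on small fixtures

smallSetup <- function(seed = 1, nPeriods = 18, hyper = NULL) {
    fx <- processModelFixture(seed = seed, nPeriods = nPeriods,
                              nSitesY = 25L, qStar = 10L,
                              gibbsSweeps = 10L)
    if (is.null(hyper))
        hyper <- HBAHyperParams(qMin = 8L, qMax = 14L, mMin = 1L, mMax = 5L)
    cache <- buildDistanceCache(fx$coeffs, fx$alignment,
                                hyper@qMin:hyper@qMax, 1,
                                c(target = fx$targetStep))
    fact <- new("NMFFactorization", basis = fx$basis,
                coef = fx$B[, seq_len(nPeriods)],
                offset = rep(0, nrow(fx$basis)),
                lossTrace = c(1, 0.5), rank = 5L, init = "custom")
    list(fx = fx, cache = cache, fact = fact, hyper = hyper)
}

test_that("the chain is a deterministic function of its seed", {
    s <- smallSetup()
    f1 <- hbaFit(s$fx$counts, s$fact, s$cache, s$hyper, 300, 100, seed = 11)
    f2 <- hbaFit(s$fx$counts, s$fact, s$cache, s$hyper, 300, 100, seed = 11)
    expect_identical(f1@q, f2@q)
    expect_identical(f1@theta1, f2@theta1)
    expect_identical(f1@logJoint, f2@logJoint)
    f3 <- hbaFit(s$fx$counts, s$fact, s$cache, s$hyper, 300, 100, seed = 12)
    expect_false(identical(f1@theta1, f3@theta1))
})

test_that("every update block mixes: acceptance rates strictly inside (0,1)", {
    s <- smallSetup(2)
    fit <- hbaFit(s$fx$counts, s$fact, s$cache, s$hyper, 2000, 400,
                  seed = 3, sampleB = TRUE)
    r <- fit@acceptRates
    expect_true(all(r > 0 & r < 1))
    expect_true(all(is.finite(fit@logJoint)))
    expect_true(all(fit@B >= 0))
    expect_true(all(fit@q >= 8 & fit@q <= 14))
    expect_true(all(fit@m >= 1 & fit@m <= 5))
    expect_true(all(fit@theta1 > 0) && all(fit@sigma2eta > 0))
})

test_that("hindcast mode drops the held-out period from pool and likelihood", {
    s <- smallSetup(3)
    hold <- 9L
    fit <- hbaFit(s$fx$counts, s$fact, s$cache, s$hyper, 300, 100,
                  seed = 5, holdout = hold)
    expect_false(hold %in% fit@pool)
    expect_equal(length(fit@pool), 17L)
})

test_that("Laplacian-eigenmap caches add a neighbor-count update", {
    fx <- processModelFixture(seed = 4, nPeriods = 16, nSitesY = 20L,
                              qStar = 8L, gibbsSweeps = 5L)
    sc <- syntheticScenario(nPeriods = 16L, seed = 4L)
    fr <- simulateForcing(sc)
    an <- computeAnomalies(fr, 1:16)
    coefs <- lapply(c(6L, 9L), function(k)
        laplacianEigenmapCoefficients(an, 3, k))
    hyper <- HBAHyperParams(qMin = 6L, qMax = 10L, mMin = 1L, mMax = 4L)
    cache <- buildDistanceCache(coefs, fx$alignment, 6:10)
    expect_equal(cache@leGrid, c(6L, 9L))
    fit <- hbaFit(fx$counts, new("NMFFactorization", basis = fx$basis,
                                 coef = fx$B[, 1:16],
                                 offset = rep(0, nrow(fx$basis)),
                                 lossTrace = c(1, .5), rank = 5L,
                                 init = "custom"),
                  cache, hyper, 400, 100, seed = 6)
    expect_true(all(fit@leK %in% c(6L, 9L)))
    expect_true("le" %in% names(fit@acceptRates))
})
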