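# synthetic scenarios and the process-model fixture

test_that("forcing is a noisy projection of the latent trajectory", {
    sc <- syntheticScenario("quasiperiodic", nSitesX = 6L, nPeriods = 10L,
                            noiseSD = 0, seed = 2)
    L <- rbind(diag(3), matrix(0, 3, 3))
    fr <- simulateForcing(sc, loadings = L)
    z <- analogcast:::latentTrajectory(sc)
    expect_equal(unname(forcingValues(fr)[1:3, ]), unname(z),
                 tolerance = 1e-12)
    # reproducibility from the scenario seed
    f1 <- simulateForcing(syntheticScenario(seed = 5, nPeriods = 6L))
    f2 <- simulateForcing(syntheticScenario(seed = 5, nPeriods = 6L))
    expect_identical(forcingValues(f1), forcingValues(f2))
    # (near-)zero-noise field has latent rank three: the fourth component
    # carries essentially no variance
    sc0 <- syntheticScenario(nSitesX = 20L, nPeriods = 10L, noiseSD = 1e-7,
                             seed = 3)
    co <- eofCoefficients(simulateForcing(sc0), 4, center = TRUE)
    expect_lt(varianceExplained(co)[4], 1e-8)
    expect_gt(varianceExplained(co)[3], 1e-8)
})

test_that("scenario labels put each period's anchor month in its own year", {
    sc <- syntheticScenario(nPeriods = 8L, seed = 1)
    fr <- simulateForcing(sc)
    lab <- stepLabels(fr)
    for (i in c(1L, 5L, 8L)) {
        s <- analogcast:::scenarioAnchor(sc, i)
        expect_equal(lab$year[s], i)
        expect_equal(lab$month[s], 5L)
    }
})

test_that("counts are Poisson at the stated intensities", {
    sc <- syntheticScenario("quasiperiodic", nSitesY = 40L, nPeriods = 60L,
                            seed = 7)
    yc <- simulateCounts(sc)
    lam <- S4Vectors::metadata(yc)$lambda
    y <- counts(yc)
    # zero intensity -> all-zero counts
    sc0 <- syntheticScenario(intensityScale = 0, nPeriods = 5L, seed = 1)
    expect_true(all(counts(simulateCounts(sc0)) == 0))
    # pooled first-moment check: mean(Y - lambda) within 3 MC s.e.
    n <- length(y)
    expect_lt(abs(mean(y - lam)), 3 * sqrt(sum(lam)) / n)
    # pooled variance check via standardized residuals (Var = lambda)
    z <- (y - lam)[lam > 0.5] / sqrt(lam[lam > 0.5])
    expect_lt(abs(mean(z^2) - 1), 5 / sqrt(length(z)))
    # zero inflation adds the stated extra-zero mass where lambda is large
    scz <- syntheticScenario("quasiperiodic", nSitesY = 60L, nPeriods = 60L,
                             intensityScale = 40, zeroInflation = 0.3,
                             seed = 8)
    ycz <- simulateCounts(scz)
    lamz <- S4Vectors::metadata(ycz)$lambda
    big <- lamz > 8
    p0 <- mean(counts(ycz)[big] == 0)
    se <- sqrt(0.3 * 0.7 / sum(big))
    expect_lt(abs(p0 - 0.3), 3 * se + 1e-3)
})

test_that("process fixture is reproducible and respects its own equations", {
    f1 <- processModelFixture(seed = 3, nPeriods = 14, nSitesY = 15L,
                              qStar = 8L, gibbsSweeps = 5L)
    f2 <- processModelFixture(seed = 3, nPeriods = 14, nSitesY = 15L,
                              qStar = 8L, gibbsSweeps = 5L)
    expect_identical(f1$B, f2$B)
    expect_identical(counts(f1$counts), counts(f2$counts))
    expect_true(all(f1$B >= 0))
    # degenerate limit: vanishing process noise with one neighbor copies
    # the nearest analog's coefficients
    fd <- processModelFixture(qStar = 8L, mStar = 1L, sigma2Star = 1e-12,
                              seed = 4, nPeriods = 14, nSitesY = 15L,
                              gibbsSweeps = 5L)
    cache <- buildDistanceCache(fd$coeffs, fd$alignment, 8L)
    for (t in c(3L, 9L, 14L)) {
        w <- kernelWeights(t, cache, 8L, 1L, fd$truth$theta1)
        nn <- which.max(w)
        relErr <- max(abs(fd$B[, t] - fd$B[, nn]) /
                      pmax(abs(fd$B[, nn]), 1e-8))
        expect_lt(relErr, 1e-3)
    }
})

test_that("analog-rich scenario guarantees a recurrent pool", {
    # every period has some pool analog much closer than the typical pair
    sc <- syntheticScenario("quasiperiodic", nPeriods = 40L, seed = 6)
    fr <- simulateForcing(sc)
    co <- eofCoefficients(computeAnomalies(fr, 1:40), 4)
    anchors <- setNames(vapply(seq_len(40), function(i)
        analogcast:::scenarioAnchor(sc, i) - sc@tau, integer(1)),
        seq_len(40))
    cache <- buildDistanceCache(co, anchors, 40L)
    d <- cache@dists[[1]][["q40"]]
    diag(d) <- NA
    nn <- apply(d, 1, min, na.rm = TRUE)
    med <- median(d, na.rm = TRUE)
    expect_lt(max(nn / med), 0.85)
    expect_lt(median(nn / med), 0.6)
})
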