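# Procrustes distances, the distance cache, and kernel analog weights

test_that("Procrustes distance has the required invariances", {
    set.seed(1)
    a <- matrix(rnorm(15), 3, 5)
    expect_equal(procrustesDistance(a, a), 0)
    # orthogonal transforms of the coordinates are matched exactly
    for (i in 1:5) {
        q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
        expect_lt(procrustesDistance(a, q %*% (a - rowMeans(a))), 1e-8)
    }
    expect_lt(procrustesDistance(a, 3.7 * a), 1e-8)         # theta2 = 1
    expect_gt(procrustesDistance(a, 3.7 * a, theta2 = 0), 1) # no scaling
    # translation of the point configuration never matters
    expect_lt(procrustesDistance(a, a + 2), 1e-8)
    expect_error(procrustesDistance(a, matrix(0, 3, 4)), "shape")
    # zero-variance comparison: documented scale-1 fallback
    expect_equal(procrustesDistance(a, matrix(1, 3, 5)),
                 sqrt(sum((a - rowMeans(a))^2)))
})

test_that("Procrustes distance agrees with the vegan oracle", {
    set.seed(2)
    for (i in 1:5) {
        a <- matrix(rnorm(24), 4, 6)
        b <- matrix(rnorm(24), 4, 6)
        pv <- vegan::procrustes(t(a), t(b), symmetric = FALSE)
        expect_equal(procrustesDistance(a, b),
                     sqrt(sum((pv$X - pv$Yrot)^2)), tolerance = 1e-10)
    }
})

test_that("distance cache matches direct distance computation", {
    co <- tinyCoeffs(3)
    anchors <- setNames(seq(40, 118, by = 6), seq_len(14))
    cache <- buildDistanceCache(co, anchors, qRange = c(5, 9), theta2 = 1,
                                targetSteps = c(t1 = 120))
    expect_equal(length(cache@pool), 14L)
    set.seed(7)
    for (i in 1:6) {
        q <- sample(c(5, 9), 1)
        tl <- sample(length(cache@pool), 2)
        d <- cache@dists[[1]][[paste0("q", q)]][tl[1], tl[2]]
        a1 <- coefMatrix(co)[, seq(anchors[tl[1]], by = -1, length.out = q)]
        a2 <- coefMatrix(co)[, seq(anchors[tl[2]], by = -1, length.out = q)]
        expect_equal(d, procrustesDistance(a1, a2), tolerance = 1e-12)
    }
    expect_true(all(diag(cache@dists[[1]][["q5"]]) == 0))
    # an exact repeat in the series gives a zero off-diagonal distance
    co2 <- tinyCoeffs(3)
    co2@coef[, 100:119] <- co2@coef[, 40:59]
    cache2 <- buildDistanceCache(co2, setNames(c(59, 119), 1:2), 20)
    expect_lt(cache2@dists[[1]][["q20"]][1, 2], 1e-10)
})

test_that("kernel weights follow the hand-evaluated formula and its limits", {
    co <- tinyCoeffs(5)
    anchors <- setNames(seq(30, 114, by = 4), seq_len(22))
    cache <- buildDistanceCache(co, anchors, qRange = 7,
                                targetSteps = c(t1 = 118))
    n <- length(cache@pool)
    # two-neighborhood: weights must equal the normalised Gaussian kernel
    d <- cache@sortD[[1]][["q7"]][3, 1:2]
    th1 <- 0.37
    w <- kernelWeights(3, cache, 7, 2, th1)
    expect_equal(sum(w), 1)
    expect_equal(sum(w > 0), 2L)
    k <- exp(-d^2 / (2 * th1))
    expected <- k / sum(k)
    expect_equal(sort(w[w > 0], decreasing = TRUE),
                 sort(expected, decreasing = TRUE), tolerance = 1e-12)
    # m = 1 concentrates all mass on the nearest analog
    w1 <- kernelWeights(3, cache, 7, 1, th1)
    expect_equal(max(w1), 1)
    # theta1 limits: uniform neighborhood vs nearest-only
    wInf <- kernelWeights(3, cache, 7, 5, 1e8)
    expect_equal(unname(wInf[wInf > 0]), rep(0.2, 5), tolerance = 1e-4)
    w0 <- kernelWeights(3, cache, 7, 5, 1e-12)
    expect_equal(max(w0), 1)
    expect_equal(which.max(w0), which.max(w1))
    expect_error(kernelWeights(3, cache, 7, n, th1), "pool")
})

test_that("weights are a law: nonnegative, sum to one, m smallest, scale-covariant", {
    co <- tinyCoeffs(11)
    anchors <- setNames(seq(30, 114, by = 4), seq_len(22))
    cache <- buildDistanceCache(co, anchors, qRange = c(4, 8))
    set.seed(11)
    for (i in 1:50) {
        q <- sample(c(4, 8), 1)
        m <- sample(1:10, 1)
        th1 <- runif(1, 0.01, 5)
        t <- sample(length(cache@pool), 1)
        w <- kernelWeights(t, cache, q, m, th1)
        expect_true(all(w >= 0))
        expect_equal(sum(w), 1, tolerance = 1e-12)
        expect_lte(sum(w > 0), m)
        # neighborhood = brute-force m smallest distances (self excluded);
        # far members may underflow to exactly zero at tiny theta1
        d <- cache@dists[[1]][[paste0("q", q)]][t, ]
        d[t] <- Inf
        nbh <- order(d)[seq_len(m)]
        expect_true(all(which(w > 0) %in% nbh))
        expect_gt(w[nbh[1]], 0)
    }
    # rescaling all distances by c with theta1 -> theta1 c^2 leaves w fixed
    cache2 <- cache
    cache2@dists <- lapply(cache@dists, function(g) lapply(g, function(d) 3 * d))
    cache2@sortD <- lapply(cache@sortD, function(g) lapply(g, function(d) 3 * d))
    w1 <- kernelWeights(4, cache, 8, 6, 0.2)
    w2 <- kernelWeights(4, cache2, 8, 6, 0.2 * 9)
    expect_equal(w1, w2, tolerance = 1e-12)
})
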