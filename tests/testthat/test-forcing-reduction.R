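# EOF and Laplacian-eigenmap coefficient series, embedding matrices

test_that("EOF coefficients equal the least-squares projection", {
    set.seed(1)
    x <- matrix(rnorm(80), 10, 8)
    co <- eofCoefficients(x, 3, center = FALSE)
    phi <- basisMatrix(co)
    oracle <- solve(crossprod(phi), crossprod(phi, x))   # (Phi'Phi)^-1 Phi'x
    expect_equal(coefMatrix(co), oracle, tolerance = 1e-10)
})

test_that("EOF variance fractions and completeness behave", {
    set.seed(2)
    r1 <- outer(rnorm(6), rnorm(9))
    co <- eofCoefficients(r1, 1, center = FALSE)
    expect_equal(varianceExplained(co)[1], 1, tolerance = 1e-10)
    x <- matrix(rnorm(48), 6, 8)
    full <- eofCoefficients(x, 6, center = TRUE)
    rec <- basisMatrix(full) %*% coefMatrix(full)
    expect_equal(rec, x - rowMeans(x), tolerance = 1e-10)
    expect_error(eofCoefficients(r1, 4, center = FALSE), "rank")
    # centering makes coefficients invariant to a constant added per step
    co1 <- eofCoefficients(x, 2, center = TRUE)
    co2 <- eofCoefficients(x + 5, 2, center = TRUE)
    expect_equal(abs(coefMatrix(co1)), abs(coefMatrix(co2)),
                 tolerance = 1e-8)
})

test_that("Laplacian eigenmap separates clusters and solves L v = lambda v", {
    set.seed(3)
    # two tight clusters (size > k so kNN stays inside them) joined only
    # through a single bridge point between them
    x <- cbind(matrix(rnorm(5 * 13, 0, 0.1), 5, 13),
               matrix(4, 5, 1) + rnorm(5, 0, 0.1),
               matrix(rnorm(5 * 13, 8, 0.1), 5, 13))
    co <- laplacianEigenmapCoefficients(x, 2, kNeighbors = 9)
    v1 <- coefMatrix(co)[1, ]
    s1 <- sign(mean(v1[1:13]))
    expect_true(s1 != 0)
    expect_true(all(v1[1:13] * s1 > 0))
    expect_true(all(v1[15:27] * s1 < 0))
    # eigen-residual against a dense oracle Laplacian
    n <- ncol(x)
    d2 <- as.matrix(dist(t(x)))^2
    w <- matrix(0, n, n)
    for (i in seq_len(n)) w[i, order(d2[i, ])[2:10]] <- 1
    w <- pmax(w, t(w))
    L <- diag(rowSums(w)) - w
    for (k in 1:2) {
        v <- coefMatrix(co)[k, ]
        lam <- drop(v %*% L %*% v) / sum(v^2)
        expect_lt(max(abs(L %*% v - lam * v)), 1e-8)
    }
    # adjacency rows keep >= k entries after union symmetrisation
    expect_true(all(rowSums(w > 0) >= 9))
    # disconnected graph is refused with guidance
    expect_error(laplacianEigenmapCoefficients(x[, -14], 2, kNeighbors = 5),
                 "kNeighbors")
})

test_that("LE coordinates are L-orthogonal and sign-stabilised", {
    set.seed(4)
    x <- matrix(rnorm(5 * 15), 5, 15)
    co <- laplacianEigenmapCoefficients(x, 3, kNeighbors = 5)
    cc <- coefMatrix(co)
    for (i in 1:2) for (j in (i + 1):3)
        expect_lt(abs(sum(cc[i, ] * cc[j, ])), 1e-8)
    for (k in 1:3)
        expect_gt(cc[k, which.max(abs(cc[k, ]))], 0)
})

test_that("embedding is the exact column-lag re-indexing", {
    a <- matrix(1:4, 1)
    e <- buildEmbedding(a, anchor = 4, q = 3)
    expect_equal(unname(e@values), matrix(c(4, 3, 2), 1))
    e1 <- buildEmbedding(a, anchor = 2, q = 1)
    expect_equal(unname(e1@values), matrix(2, 1))
    set.seed(5)
    big <- matrix(rnorm(16 * 80), 16, 80)
    e2 <- buildEmbedding(big, anchor = 70, q = 50)
    expect_equal(dim(e2@values), c(16L, 50L))
    expect_equal(e2@values[, 17], big[, 70 - 16])   # pure re-indexing
    expect_error(buildEmbedding(a, anchor = 2, q = 3), "history")
})
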