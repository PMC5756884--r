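# Forcing-field dimension reduction: EOF (linear) and Laplacian eigenmap
# (nonlinear, nearest-neighbor graph) coefficient series, and the time-lagged
# embedding matrices built from them.

#' Empirical orthogonal function coefficients of a forcing field
#'
#' Decomposes the (optionally temporally centered) anomaly matrix with the
#' SVD: the spatial basis is the leading left singular vectors and, the basis
#' being orthonormal, the coefficient series is its plain projection
#' `alpha_t' = Phi' x_t'` (the general least-squares projection
#' `(Phi'Phi)^{-1} Phi' x` reduces to this). Per-component variance fractions
#' are reported.
#'
#' @param anomalies a [ForcingSeries-class] (usually from
#'   [computeAnomalies()]) or a plain sites x steps matrix.
#' @param nAlpha number of components to keep.
#' @param center remove the per-site temporal mean first (default TRUE;
#'   monthly anomalies retain a small residual mean over any finite span).
#' @return a [ForcingCoefficients-class] with method `"EOF"`.
#' @export
eofCoefficients <- function(anomalies, nAlpha, center = TRUE) {
    lab <- if (is(anomalies, "ForcingSeries")) stepLabels(anomalies)
    x <- if (is(anomalies, "ForcingSeries")) forcingValues(anomalies)
         else as.matrix(anomalies)
    stopifnot(all(is.finite(x)))
    if (center) x <- x - rowMeans(x)
    nAlpha <- as.integer(nAlpha)
    sv <- svd(x)
    rk <- sum(sv$d > max(dim(x)) * .Machine$double.eps * max(sv$d, 1))
    if (nAlpha > rk)
        stop("nAlpha = ", nAlpha, " exceeds the matrix rank (", rk, ")")
    phi <- sv$u[, seq_len(nAlpha), drop = FALSE]
    alpha <- crossprod(phi, x)
    ve <- sv$d^2 / sum(sv$d^2)
    new("ForcingCoefficients", coef = alpha, method = "EOF", basis = phi,
        varianceExplained = ve[seq_len(nAlpha)], leNeighbors = NA_integer_,
        stepYear = if (is.null(lab)) integer(0) else lab$year,
        stepMonth = if (is.null(lab)) integer(0) else lab$month)
}

#' Laplacian eigenmap coefficients of a forcing field
#'
#' Embeds the time steps (each step's spatial field is one point) with the
#' nearest-neighbor graph construction: a symmetric k-NN adjacency (union
#' rule, binary weights) on Euclidean distances between steps, the
#' unnormalized graph Laplacian `L = D - W`, and the eigenvectors of the
#' `nAlpha` smallest nonzero eigenvalues as coordinate rows. A disconnected
#' graph (zero eigenvalue of multiplicity > 1) is an error asking for a
#' larger `k`. Each coordinate vector is flipped so its largest-magnitude
#' entry is positive, removing eigenvector sign ambiguity.
#'
#' @param anomalies a [ForcingSeries-class] or sites x steps matrix.
#' @param nAlpha number of embedding coordinates.
#' @param kNeighbors neighbors per point in the k-NN graph.
#' @return a [ForcingCoefficients-class] with method `"LaplacianEigenmap"`.
#' @export
laplacianEigenmapCoefficients <- function(anomalies, nAlpha, kNeighbors) {
    lab <- if (is(anomalies, "ForcingSeries")) stepLabels(anomalies)
    x <- if (is(anomalies, "ForcingSeries")) forcingValues(anomalies)
         else as.matrix(anomalies)
    stopifnot(kNeighbors >= 1)
    n <- ncol(x)
    nAlpha <- as.integer(nAlpha)
    if (nAlpha > n - 1L) stop("nAlpha must be < number of steps")
    d2 <- as.matrix(stats::dist(t(x)))^2
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
        nb <- order(d2[i, ])[2:(kNeighbors + 1L)]
        w[i, nb] <- 1
    }
    w <- pmax(w, t(w))                       # union symmetrisation
    lap <- diag(rowSums(w)) - w
    eg <- eigen(lap, symmetric = TRUE)
    ev <- rev(eg$values)
    vec <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
    zeroTol <- 1e-8 * max(ev)
    nZero <- sum(ev < zeroTol)
    if (nZero > 1L)
        stop("k-NN graph is disconnected (", nZero,
             " components); increase kNeighbors")
    keep <- seq.int(nZero + 1L, length.out = nAlpha)
    coefs <- t(vec[, keep, drop = FALSE])
    flip <- apply(coefs, 1L, function(v) sign(v[which.max(abs(v))]))
    coefs <- coefs * flip
    new("ForcingCoefficients", coef = coefs, method = "LaplacianEigenmap",
        basis = matrix(0, 0, 0), varianceExplained = numeric(0),
        leNeighbors = as.integer(kNeighbors),
        stepYear = if (is.null(lab)) integer(0) else lab$year,
        stepMonth = if (is.null(lab)) integer(0) else lab$month)
}

#' Build a time-lagged embedding matrix
#'
#' Pure re-indexing of the coefficient series into the components x depth
#' matrix `[alpha_t', alpha_t'-1, ..., alpha_t'-(q-1)]` anchored at step
#' `anchor`: column j holds the coefficients j - 1 steps behind the anchor.
#'
#' @param coeffs a [ForcingCoefficients-class] or components x steps matrix.
#' @param anchor integer step index of the leading column.
#' @param q embedding depth (number of lags).
#' @return an [EmbeddingMatrix-class].
#' @export
buildEmbedding <- function(coeffs, anchor, q) {
    a <- if (is(coeffs, "ForcingCoefficients")) coefMatrix(coeffs)
         else as.matrix(coeffs)
    anchor <- as.integer(anchor); q <- as.integer(q)
    if (anchor - (q - 1L) < 1L)
        stop("insufficient history for anchor ", anchor, " at depth ", q)
    if (anchor > ncol(a))
        stop("anchor ", anchor, " beyond the last step")
    new("EmbeddingMatrix",
        values = a[, seq.int(anchor, by = -1L, length.out = q), drop = FALSE],
        anchor = anchor, depth = q)
}
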