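# Procrustes distances between embedding matrices, nearest-analog
# neighborhoods, and normalized Gaussian-kernel analog weights.

#' Procrustes distance between two embedding matrices
#'
#' Treats the q columns of each components x q embedding matrix as q points.
#' Both configurations are centered; the comparison is then rotated (full
#' orthogonal group — reflections allowed, the standard Procrustes solution)
#' and, when `theta2 = 1`, isotropically rescaled to minimise the Frobenius
#' distance to the target; the minimised norm is returned. Comparing shapes
#' rather than raw coordinates matches trajectories that revisit the same
#' region of phase space along a similar path. `theta2` selects the transform
#' family: 1 = full Procrustes (scaling included, so `d(A, cA) = 0`),
#' 0 = rotation + translation only. A zero-variance comparison (all columns
#' equal) cannot be scaled and falls back to scale 1.
#'
#' @param target,comparison matrices of identical shape (components x q).
#' @param theta2 transform-family selector, 1 (default) or 0.
#' @return nonnegative Procrustes distance.
#' @examples
#' a <- matrix(rnorm(12), 3, 4)
#' procrustesDistance(a, 2 * a)   # 0: scaling is in the family
#' @export
procrustesDistance <- function(target, comparison, theta2 = 1) {
    x <- if (is(target, "EmbeddingMatrix")) target@values else target
    y <- if (is(comparison, "EmbeddingMatrix")) comparison@values
         else comparison
    if (!all(dim(x) == dim(y))) stop("embedding matrices must share shape")
    xc <- x - rowMeans(x)
    yc <- y - rowMeans(y)
    ssx <- sum(xc^2)
    ssy <- sum(yc^2)
    if (ssy < .Machine$double.eps * max(ssx, 1))
        return(sqrt(ssx))                       # degenerate: scale fixed at 1
    traceS <- sum(svd(tcrossprod(xc, yc))$d)    # nuclear norm of X Y'
    d2 <- if (theta2 >= 1) ssx - traceS^2 / ssy
          else ssx + ssy - 2 * traceS
    # clamp cancellation noise so exact invariances give exactly zero
    if (d2 < 1e-12 * ssx) d2 <- 0
    sqrt(max(d2, 0))
}

# Internal: pairwise Procrustes distances between embeddings anchored at
# `anchors` (and optional `targetAnchors`), at one depth q.
procrustesDistanceMatrix <- function(alpha, anchors, q, theta2,
                                     targetAnchors = integer(0)) {
    n <- length(anchors)
    emb <- lapply(anchors, function(s) {
        e <- alpha[, seq.int(s, by = -1L, length.out = q), drop = FALSE]
        e - rowMeans(e)
    })
    ss <- vapply(emb, function(e) sum(e^2), numeric(1))
    dmat <- matrix(0, n, n)
    # with optimal scaling the distance is asymmetric (the comparison is
    # transformed onto the target); one SVD serves both orientations since
    # the cross-product nuclear norm is shared. Row = target, column =
    # comparison.
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (theta2 >= 1) {
            traceS <- sum(svd(tcrossprod(emb[[i]], emb[[j]]))$d)
            dij <- ss[i] - traceS^2 / max(ss[j], .Machine$double.xmin)
            dji <- ss[j] - traceS^2 / max(ss[i], .Machine$double.xmin)
            dmat[i, j] <- sqrt(max(ifelse(dij < 1e-12 * ss[i], 0, dij), 0))
            dmat[j, i] <- sqrt(max(ifelse(dji < 1e-12 * ss[j], 0, dji), 0))
        } else {
            dmat[i, j] <- dmat[j, i] <- centeredProcrustes(
                emb[[i]], emb[[j]], ss[i], ss[j], theta2)
        }
    }
    tmat <- NULL
    if (length(targetAnchors)) {
        tmat <- matrix(0, length(targetAnchors), n)
        for (k in seq_along(targetAnchors)) {
            e <- alpha[, seq.int(targetAnchors[k], by = -1L,
                                 length.out = q), drop = FALSE]
            e <- e - rowMeans(e)
            sse <- sum(e^2)
            for (j in seq_len(n))
                tmat[k, j] <- centeredProcrustes(e, emb[[j]], sse, ss[j],
                                                 theta2)
        }
    }
    list(dist = dmat, target = tmat)
}

# core on pre-centered configurations (distance is asymmetric in general:
# the comparison is transformed onto the target)
centeredProcrustes <- function(xc, yc, ssx, ssy, theta2) {
    if (ssy < .Machine$double.eps * max(ssx, 1)) return(sqrt(ssx))
    traceS <- sum(svd(tcrossprod(xc, yc))$d)
    d2 <- if (theta2 >= 1) ssx - traceS^2 / ssy
          else ssx + ssy - 2 * traceS
    if (d2 < 1e-12 * ssx) d2 <- 0
    sqrt(max(d2, 0))
}

#' Precompute Procrustes distances over the analog pool
#'
#' Builds, for every embedding depth q in `qRange` (and every Laplacian-
#' eigenmap neighbor-grid value when a list of coefficient sets is supplied),
#' the pool x pool distance matrix between embedding matrices, so the MCMC
#' sampler only switches between cached matrices. The pool is restricted to
#' periods whose anchored step has `max(qRange) - 1` earlier steps. Forecast
#' target anchors may be included; their distances to the pool are cached
#' alongside.
#'
#' @param coeffs a [ForcingCoefficients-class], or a list of them (one per LE
#'   neighbor-grid value).
#' @param alignment an [AlignmentSpec-class] from [alignPeriods()], or a named
#'   integer vector of anchor steps per period.
#' @param qRange integer vector of depths to cache.
#' @param theta2 Procrustes family selector (see [procrustesDistance()]).
#' @param targetSteps named integer vector of forecast-target anchor steps.
#' @return a [DistanceCache-class].
#' @export
buildDistanceCache <- function(coeffs, alignment, qRange, theta2 = 1,
                               targetSteps = integer(0)) {
    anchors <- if (is(alignment, "AlignmentSpec")) alignment@periodToStep
               else alignment
    qRange <- as.integer(sort(qRange))
    qMax <- max(qRange)
    pool <- which(anchors - (qMax - 1L) >= 1L)
    if (length(pool) == 0L) stop("empty analog pool at qMax = ", qMax)
    if (length(targetSteps) && any(targetSteps - (qMax - 1L) < 1L))
        stop("target anchor lacks qMax history")
    coefList <- if (is(coeffs, "ForcingCoefficients")) list(coeffs) else coeffs
    leGrid <- if (length(coefList) > 1L || !is.na(coefList[[1L]]@leNeighbors))
        vapply(coefList, function(cc) cc@leNeighbors, integer(1))
    else integer(0)
    n <- length(pool)
    dists <- sortIdx <- sortD <- targetD <- targetSortIdx <-
        vector("list", length(coefList))
    for (g in seq_along(coefList)) {
        alpha <- coefMatrix(coefList[[g]])
        dq <- siq <- sdq <- tq <- tiq <- list()
        for (q in qRange) {
            pm <- procrustesDistanceMatrix(alpha, anchors[pool], q, theta2,
                                           targetSteps)
            key <- paste0("q", q)
            dq[[key]] <- pm$dist
            # per-row neighbor order excluding self; ties -> smaller period
            si <- matrix(0L, n, n - 1L)
            sd <- matrix(0, n, n - 1L)
            for (i in seq_len(n)) {
                o <- order(pm$dist[i, -i])
                si[i, ] <- (seq_len(n)[-i])[o]
                sd[i, ] <- (pm$dist[i, -i])[o]
            }
            siq[[key]] <- si
            sdq[[key]] <- sd
            if (length(targetSteps)) {
                tq[[key]] <- pm$target
                tiq[[key]] <- t(apply(pm$target, 1L, order))
            }
        }
        dists[[g]] <- dq; sortIdx[[g]] <- siq; sortD[[g]] <- sdq
        targetD[[g]] <- tq; targetSortIdx[[g]] <- tiq
    }
    names(dists) <- names(sortIdx) <- names(sortD) <- names(targetD) <-
        names(targetSortIdx) <-
        if (length(leGrid)) paste0("k", leGrid) else "eof"
    new("DistanceCache", dists = dists, sortIdx = sortIdx, sortD = sortD,
        targetD = targetD, targetSortIdx = targetSortIdx,
        pool = as.integer(pool), qRange = qRange, leGrid = leGrid,
        theta2 = theta2,
        targets = if (length(targetSteps)) names(targetSteps) else character(0))
}

# internal list accessor: grid entry for LE value k (or the single EOF entry)
cacheEntry <- function(cache, what, le = NULL) {
    lst <- slot(cache, what)
    if (length(cache@leGrid) == 0L) lst[[1L]]
    else lst[[paste0("k", le)]]
}

#' Normalized Gaussian-kernel analog weights
#'
#' Weights each pool period by `exp(-d^2 / (2 theta1))` inside the m-nearest
#' neighborhood of the target embedding and 0 outside, normalized to sum to
#' one over the candidate analogs. For a training period the candidate set
#' excludes the period itself; for a forecast target all pool periods are
#' candidates. Ties at the m-th neighbor break toward the smaller period
#' index. As `theta1 -> Inf` the weights tend to uniform over the
#' neighborhood; as `theta1 -> 0+` all mass moves to the single nearest
#' analog.
#'
#' @param t index of the target within the pool (for `excludeSelf = TRUE`) or
#'   within the cached forecast targets (for `excludeSelf = FALSE`).
#' @param cache a [DistanceCache-class].
#' @param q embedding depth (must be cached).
#' @param m neighborhood size.
#' @param theta1 positive kernel smoothing parameter.
#' @param excludeSelf TRUE for training weights, FALSE for forecast targets.
#' @param le Laplacian-eigenmap grid value (when the cache holds an LE grid).
#' @return numeric weight vector over the pool, summing to 1, with at most m
#'   nonzero entries.
#' @export
kernelWeights <- function(t, cache, q, m, theta1, excludeSelf = TRUE,
                          le = NULL) {
    stopifnot(m >= 1, theta1 > 0)
    key <- paste0("q", q)
    n <- length(cache@pool)
    if (excludeSelf) {
        if (m > n - 1L) stop("m exceeds the pool size after self-exclusion")
        si <- cacheEntry(cache, "sortIdx", le)[[key]]
        sd <- cacheEntry(cache, "sortD", le)[[key]]
        if (is.null(sd)) stop("depth q = ", q, " not cached")
        idx <- si[t, seq_len(m)]
        d <- sd[t, seq_len(m)]
    } else {
        if (m > n) stop("m exceeds the pool size")
        td <- cacheEntry(cache, "targetD", le)[[key]]
        if (is.null(td)) stop("depth q = ", q, " not cached")
        ti <- cacheEntry(cache, "targetSortIdx", le)[[key]]
        idx <- ti[t, seq_len(m)]
        d <- td[t, idx]
    }
    # subtract the neighborhood minimum before exponentiating: exact under
    # the normalisation, and keeps theta1 -> 0 well defined
    wt <- exp(-(d^2 - d[1L]^2) / (2 * theta1))
    w <- numeric(n)
    w[idx] <- wt / sum(wt)
    w
}

# Internal: full training weight matrix W (pool x pool, zero diagonal,
# rows sum to 1) for given (q, m, theta1), from the sorted cache.
weightMatrix <- function(cache, q, m, theta1, le = NULL) {
    key <- paste0("q", q)
    si <- cacheEntry(cache, "sortIdx", le)[[key]]
    sd <- cacheEntry(cache, "sortD", le)[[key]]
    n <- nrow(si)
    idx <- si[, seq_len(m), drop = FALSE]
    d <- sd[, seq_len(m), drop = FALSE]
    wt <- exp(-(d^2 - d[, 1L]^2) / (2 * theta1))
    wt <- wt / rowSums(wt)
    w <- matrix(0, n, n)
    w[cbind(rep(seq_len(n), m), as.vector(idx))] <- as.vector(wt)
    w
}

# Internal: forecast weights for target row t over all pool periods.
targetWeights <- function(cache, t, q, m, theta1, le = NULL) {
    kernelWeights(t, cache, q, m, theta1, excludeSelf = FALSE, le = le)
}
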