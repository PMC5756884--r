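# Nonnegative dimension reduction of the count field: deterministic NNSVD
# initialisation and offset-NMF multiplicative updates under squared
# Frobenius loss (no regularisation term).

#' Nonnegative double SVD initialisation
#'
#' Deterministic starting values for NMF built from the singular value
#' decomposition. The leading factor pair uses the (entrywise nonnegative)
#' first singular triplet; each later pair keeps the dominant sign-consistent
#' part of its triplet — whichever of the positive or negative parts of
#' `(u_j, v_j)` carries more mass — scaled to preserve the singular value.
#' Zeros produced by the sign split are kept (the sparse-friendly variant),
#' which suits zero-heavy count fields. Being SVD-based, the result is
#' identical on every call.
#'
#' @param y nonnegative matrix, sites x periods.
#' @param rank integer, `1 <= rank <= min(dim(y))`.
#' @return list with nonnegative matrices `basis` (sites x rank) and
#'   `coef` (rank x periods).
#' @references Boutsidis & Gallopoulos (2008), Pattern Recognition 41:
#'   SVD-based initialisation for nonnegative matrix factorization.
#' @export
nnsvdInit <- function(y, rank) {
    y <- as.matrix(y) * 1.0
    if (any(y < 0)) stop("y must be nonnegative")
    rank <- as.integer(rank)
    if (rank < 1L || rank > min(dim(y)))
        stop("rank out of range 1..min(dim(y))")
    sv <- svd(y, nu = rank, nv = rank)
    w <- matrix(0, nrow(y), rank)
    h <- matrix(0, rank, ncol(y))
    w[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
    h[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
    for (j in seq_len(rank)[-1L]) {
        u <- sv$u[, j]; v <- sv$v[, j]
        up <- pmax(u, 0); un <- pmax(-u, 0)
        vp <- pmax(v, 0); vn <- pmax(-v, 0)
        nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
        nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
        if (nup * nvp >= nun * nvn) {
            sig <- sv$d[j] * nup * nvp
            if (sig > 0) {
                w[, j] <- sqrt(sig) * up / nup
                h[j, ] <- sqrt(sig) * vp / nvp
            }
        } else {
            sig <- sv$d[j] * nun * nvn
            w[, j] <- sqrt(sig) * un / nun
            h[j, ] <- sqrt(sig) * vn / nvn
        }
    }
    list(basis = w, coef = h)
}

#' Fit an offset nonnegative matrix factorization
#'
#' Solves `min ||Y - Psi B - b 1'||_F^2` over `Psi, B, b >= 0` by
#' multiplicative updates, the offset variant of the Lee-Seung scheme: a
#' shared nonnegative per-site offset `b` absorbs the baseline so the rank-
#' limited part captures departures from it. Each update is a
#' majorise-minimise step, so the objective trace is non-increasing; an
#' increase beyond numerical slack aborts with an internal error. With
#' `offset = FALSE` the offset is pinned at zero, giving the plain
#' factorization `Y ~ Psi B`.
#'
#' @param y nonnegative matrix, sites x periods.
#' @param rank factorization rank (must be < number of sites).
#' @param init optional list `(basis, coef)` of nonnegative starting values;
#'   default [nnsvdInit()].
#' @param offset logical: estimate the shared offset vector?
#' @param maxIter maximum update sweeps (default 5000).
#' @param tol relative objective change declaring convergence (default 1e-6).
#' @param zeroFill zeros in the starting values are raised to
#'   `zeroFill * mean(y)` before iterating (default 0.01, the NNDSVDa
#'   convention): exact zeros are absorbing under multiplicative updates, so
#'   the iteration could otherwise never leave the initial support.
#' @return an [NMFFactorization-class].
#' @references Badea (2008), Pacific Symposium on Biocomputing: offset
#'   simultaneous NMF.
#' @examples
#' y <- matrix(rpois(60, 4), 10, 6)
#' f <- fitOffsetNMF(y, rank = 2)
#' range(basisMatrix(f))   # all >= 0
#' @export
fitOffsetNMF <- function(y, rank, init = NULL, offset = TRUE,
                         maxIter = 5000L, tol = 1e-6, zeroFill = 0.01) {
    y <- as.matrix(y) * 1.0
    if (any(y < 0)) stop("y must be nonnegative")
    stopifnot(tol > 0)
    rank <- as.integer(rank)
    if (rank >= nrow(y)) stop("rank must be < number of sites")
    initName <- if (is.null(init)) "nnsvd" else "custom"
    if (is.null(init)) init <- nnsvdInit(y, rank)
    w <- init$basis; h <- init$coef
    if (any(w < 0) || any(h < 0)) stop("init must be nonnegative")
    floorPos <- zeroFill * max(mean(y), .Machine$double.xmin)
    w <- pmax(w, floorPos); h <- pmax(h, floorPos)
    b <- if (offset) pmax(apply(y, 1L, min), floorPos) else rep(0, nrow(y))
    guard <- 1e-12
    fit <- w %*% h + b
    loss <- sum((y - fit)^2)
    trace <- numeric(maxIter + 1L)
    trace[1L] <- loss
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        w <- w * (y %*% t(h)) / pmax(fit %*% t(h), guard)
        fit <- w %*% h + b
        h <- h * crossprod(w, y) / pmax(crossprod(w, fit), guard)
        fit <- w %*% h + b
        if (offset) {
            b <- b * rowSums(y) / pmax(rowSums(fit), guard)
            fit <- w %*% h + b
        }
        newLoss <- sum((y - fit)^2)
        if (newLoss > loss + 1e-10 * max(loss, 1))
            stop("internal error: objective increased at iteration ", it)
        trace[it + 1L] <- newLoss
        if (loss - newLoss < tol * max(loss, .Machine$double.xmin)) {
            loss <- newLoss
            break
        }
        loss <- newLoss
    }
    new("NMFFactorization", basis = w, coef = h, offset = as.numeric(b),
        lossTrace = trace[seq_len(it + 1L)], rank = rank, init = initName)
}

#' Site-level intensity from factorized coefficients
#'
#' `lambda_t = Psi beta_t + b`; with the offset disabled (`b = 0`) this is the
#' plain basis expansion of the count intensities.
#'
#' @param basis nonnegative matrix, sites x rank, or an
#'   [NMFFactorization-class] (in which case `offset` is taken from it).
#' @param beta nonnegative coefficient vector (or rank x k matrix).
#' @param offset nonnegative per-site offset vector (default zero).
#' @return nonnegative intensity vector/matrix over sites.
#' @export
intensity <- function(basis, beta, offset = NULL) {
    if (is(basis, "NMFFactorization")) {
        if (is.null(offset)) offset <- offsetVector(basis)
        basis <- basisMatrix(basis)
    }
    if (is.null(offset)) offset <- rep(0, nrow(basis))
    if (any(beta < 0)) stop("beta must be nonnegative")
    drop(basis %*% beta + offset)
}
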