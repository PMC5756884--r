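#' @import methods
#' @importFrom stats dnorm pnorm dpois rpois rnorm runif rgamma quantile sd
#'   uniroot integrate cor qnorm rWishart setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
NULL

#' SpaceTimeCounts: a count field over sites and periods
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for a
#' nonnegative integer count matrix with rows = survey sites and columns =
#' periods (e.g. survey years). Site longitude/latitude live in `rowData`,
#' ordered period labels in `colData$period`.
#'
#' @slot .Data inherited SummarizedExperiment structure; the single assay is
#'   named `"counts"`.
#' @export
setClass("SpaceTimeCounts", contains = "SummarizedExperiment")

setValidity("SpaceTimeCounts", function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        y <- assay(object, "counts")
        if (anyNA(y) || any(y < 0) || any(y != round(y)))
            msg <- c(msg, "counts must be nonnegative integers with no NA")
    }
    if (!all(c("lon", "lat") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain 'lon' and 'lat'")
    if (!("period" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain 'period'")
    else if (is.unsorted(colData(object)$period, strictly = TRUE))
        msg <- c(msg, "period labels must be strictly increasing")
    if (nrow(object) < 1L || ncol(object) < 3L)
        msg <- c(msg, "need at least 1 site and 3 periods")
    if (is.null(msg)) TRUE else msg
})

#' ForcingSeries: a real-valued forcing field over sites and sub-period steps
#'
#' SummarizedExperiment-derived container for a forcing (predictor) field:
#' rows = forcing grid sites, columns = time steps on a finer resolution than
#' the response periods (e.g. months). `colData` holds `year` and `month`;
#' steps must be strictly increasing and equally spaced in month units.
#'
#' @export
setClass("ForcingSeries", contains = "SummarizedExperiment")

setValidity("ForcingSeries", function(object) {
    msg <- NULL
    if (!("values" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'values' is required")
    else if (!all(is.finite(assay(object, "values"))))
        msg <- c(msg, "forcing values must be finite (missing cells are not allowed)")
    if (!all(c("lon", "lat") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain 'lon' and 'lat'")
    cd <- colData(object)
    if (!all(c("year", "month") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'year' and 'month'")
    else {
        idx <- 12L * cd$year + (cd$month - 1L)
        if (ncol(object) > 1L && !all(diff(idx) == diff(idx)[1L] & diff(idx) > 0))
            msg <- c(msg, "steps must be strictly increasing and equally spaced")
    }
    if (is.null(msg)) TRUE else msg
})

#' AlignmentSpec: response-period to forcing-step alignment
#'
#' Maps each response period to the forcing step anchoring its embedding
#' matrix: the step of the anchor sub-period (e.g. May) in that period, minus
#' the forecast lead `tau` (in forcing steps). Periods whose anchored step
#' lacks `qMax - 1` earlier steps are flagged for pool exclusion.
#'
#' @slot tau nonnegative integer forecast lead, in forcing steps.
#' @slot anchorMonth integer month used as anchor sub-period.
#' @slot periodToStep named integer vector: forcing step index per period.
#' @slot flagged logical vector: TRUE where history is insufficient.
#' @slot climWindow integer range of years used for the monthly climatology.
#' @export
setClass("AlignmentSpec", representation(
    tau = "integer", anchorMonth = "integer", periodToStep = "integer",
    flagged = "logical", climWindow = "integer"))

setValidity("AlignmentSpec", function(object) {
    if (object@tau < 0L) "tau must be >= 0" else TRUE
})

#' NMFFactorization: offset nonnegative matrix factorization of a count field
#'
#' Holds the nonnegative basis `Psi` (sites x rank), coefficients
#' `B = [beta_1, ..., beta_T]` (rank x periods), an optional shared nonnegative
#' offset vector (sites), and the per-iteration objective trace.
#'
#' @slot basis nonnegative matrix, sites x rank.
#' @slot coef nonnegative matrix, rank x periods.
#' @slot offset nonnegative numeric vector of length sites (all zero when the
#'   offset term is disabled).
#' @slot lossTrace numeric, squared-Frobenius objective per iteration.
#' @slot rank integer factorization rank.
#' @slot init character, initialisation method.
#' @export
setClass("NMFFactorization", representation(
    basis = "matrix", coef = "matrix", offset = "numeric",
    lossTrace = "numeric", rank = "integer", init = "character"))

setValidity("NMFFactorization", function(object) {
    msg <- NULL
    if (any(object@basis < 0) || any(object@coef < 0) || any(object@offset < 0))
        msg <- c(msg, "factors must be nonnegative")
    if (object@rank >= nrow(object@basis))
        msg <- c(msg, "rank must be smaller than the number of sites")
    if (length(object@lossTrace) > 1L) {
        d <- diff(object@lossTrace)
        if (any(d > 1e-10 * pmax(object@lossTrace[-length(object@lossTrace)], 1)))
            msg <- c(msg, "loss trace must be non-increasing")
    }
    if (is.null(msg)) TRUE else msg
})

#' ForcingCoefficients: reduced forcing coefficient series
#'
#' Coefficient series `alpha` (components x steps) from EOF, Laplacian
#' eigenmap, or kernel PCA reduction of a forcing field, plus method metadata.
#'
#' @slot coef matrix, components x steps.
#' @slot method one of `"EOF"`, `"LaplacianEigenmap"`, `"KPCA"`.
#' @slot basis spatial basis (sites x components) for EOF/KPCA; 0 x 0 for LE.
#' @slot varianceExplained per-component variance fractions (EOF only).
#' @slot leNeighbors integer neighbor count (LE only; `NA` otherwise).
#' @slot stepYear,stepMonth integer step labels carried from the forcing field.
#' @export
setClass("ForcingCoefficients", representation(
    coef = "matrix", method = "character", basis = "matrix",
    varianceExplained = "numeric", leNeighbors = "integer",
    stepYear = "integer", stepMonth = "integer"))

setValidity("ForcingCoefficients", function(object) {
    msg <- NULL
    if (!object@method %in% c("EOF", "LaplacianEigenmap", "KPCA"))
        msg <- c(msg, "unknown method")
    v <- object@varianceExplained
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12) || is.unsorted(rev(v))))
        msg <- c(msg, "variance fractions must be in [0,1], non-increasing")
    if (is.null(msg)) TRUE else msg
})

#' EmbeddingMatrix: time-lagged embedding of forcing coefficients
#'
#' The components x depth matrix `[alpha_t', alpha_t'-1, ..., alpha_t'-(q-1)]`
#' anchored at forcing step `t'`: a Takens-style state-space reconstruction of
#' the forcing trajectory.
#'
#' @slot values matrix, components x depth; column j holds the coefficients at
#'   lag j - 1 behind the anchor.
#' @slot anchor integer forcing step index of column 1.
#' @slot depth integer number of lags q.
#' @export
setClass("EmbeddingMatrix", representation(
    values = "matrix", anchor = "integer", depth = "integer"))

setValidity("EmbeddingMatrix", function(object) {
    if (ncol(object@values) != object@depth)
        "depth must equal the number of columns" else TRUE
})

#' DistanceCache: precomputed Procrustes distances over the analog pool
#'
#' For each embedding depth q (and, for Laplacian-eigenmap reductions, each
#' neighbor-grid value) stores the pool x pool Procrustes distance matrix
#' between embedding matrices, the per-row neighbor ordering used for
#' m-nearest neighborhoods (ties broken by smaller period index), and the
#' distances from each forecast target embedding to the pool.
#'
#' @slot dists list over LE grid values (length 1 otherwise), each a list over
#'   q of pool x pool distance matrices.
#' @slot sortIdx,sortD same nesting: per-row neighbor index order excluding
#'   self, and the matching sorted distances.
#' @slot targetD list over LE grid, each a list over q of matrices
#'   (targets x pool) of target-to-pool distances.
#' @slot targetSortIdx same nesting: per-target pool ordering (self included).
#' @slot pool integer period indices with full embeddings.
#' @slot qRange integer vector of cached depths.
#' @slot leGrid integer vector of cached LE neighbor counts (length 0 for EOF).
#' @slot theta2 numeric in {0,1}: 1 = full Procrustes (optimal isotropic
#'   scaling), 0 = rotation + translation only.
#' @slot targets character labels of the forecast targets.
#' @export
setClass("DistanceCache", representation(
    dists = "list", sortIdx = "list", sortD = "list",
    targetD = "list", targetSortIdx = "list",
    pool = "integer", qRange = "integer", leGrid = "integer",
    theta2 = "numeric", targets = "character"))

#' HBAHyperParams: hyperparameters of the hierarchical analog model
#'
#' Defaults follow the reference analysis: mean floor `eps = 1e-6`, depth
#' prior q ~ DU(30, 60), neighborhood prior m ~ DU(1, 15), kernel smoothing
#' theta1 ~ IG(2.02, 0.102), process variance sigma2eta ~ IG(0.001, 0.001),
#' and full-Procrustes distances (`theta2 = 1`).
#'
#' @slot eps mean floor applied after bias correction.
#' @slot qMin,qMax discrete-uniform support for the embedding depth.
#' @slot mMin,mMax discrete-uniform support for the neighborhood size.
#' @slot a1,b1 inverse-gamma shape/scale for the kernel parameter theta1.
#' @slot a2,b2 inverse-gamma shape/scale for the process variance.
#' @slot theta2 Procrustes transform-family selector (1 = with scaling).
#' @export
setClass("HBAHyperParams", representation(
    eps = "numeric", qMin = "integer", qMax = "integer",
    mMin = "integer", mMax = "integer",
    a1 = "numeric", b1 = "numeric", a2 = "numeric", b2 = "numeric",
    theta2 = "numeric"))

setValidity("HBAHyperParams", function(object) {
    msg <- NULL
    if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
    if (object@qMin > object@qMax) msg <- c(msg, "qMin must be <= qMax")
    if (object@mMin > object@mMax) msg <- c(msg, "mMin must be <= mMax")
    if (any(c(object@a1, object@b1, object@a2, object@b2) <= 0))
        msg <- c(msg, "inverse-gamma parameters must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct hyperparameters for the hierarchical analog model
#'
#' @param eps mean floor (default `1e-6`).
#' @param qMin,qMax embedding-depth prior support (default 30, 60).
#' @param mMin,mMax neighborhood-size prior support (default 1, 15).
#' @param a1,b1 inverse-gamma prior for the kernel smoothing parameter
#'   (default 2.02, 0.102 — prior mean about 0.1).
#' @param a2,b2 inverse-gamma prior for the process variance (default
#'   0.001, 0.001, essentially noninformative).
#' @param theta2 Procrustes family selector: 1 includes optimal isotropic
#'   scaling, 0 fixes scaling at 1.
#' @return an [HBAHyperParams-class] object.
#' @export
HBAHyperParams <- function(eps = 1e-6, qMin = 30L, qMax = 60L,
                           mMin = 1L, mMax = 15L,
                           a1 = 2.02, b1 = 0.102, a2 = 0.001, b2 = 0.001,
                           theta2 = 1) {
    new("HBAHyperParams", eps = eps, qMin = as.integer(qMin),
        qMax = as.integer(qMax), mMin = as.integer(mMin),
        mMax = as.integer(mMax), a1 = a1, b1 = b1, a2 = a2, b2 = b2,
        theta2 = theta2)
}

#' HBAPosterior: retained MCMC draws from the hierarchical analog model
#'
#' @slot q,m integer draws of embedding depth and neighborhood size.
#' @slot theta1,sigma2eta,logJoint numeric draws.
#' @slot leK integer draws of the Laplacian-eigenmap neighbor count (length 0
#'   for EOF-based fits).
#' @slot B array rank x periods x draws of coefficient samples.
#' @slot acceptRates named numeric acceptance rates per update block.
#' @slot hyper the [HBAHyperParams-class] used.
#' @slot pool integer period indices used for training.
#' @slot seed integer RNG seed.
#' @export
setClass("HBAPosterior", representation(
    q = "integer", m = "integer", theta1 = "numeric", sigma2eta = "numeric",
    leK = "integer", B = "array", logJoint = "numeric",
    acceptRates = "numeric", hyper = "HBAHyperParams", pool = "integer",
    seed = "integer"))

#' ForecastResult: posterior-predictive forecast draws and summaries
#'
#' Shared output schema of the analog model and the Poisson space-time
#' baseline, so forecast evaluation is model-agnostic.
#'
#' @slot draws integer matrix, sites x retained draws, of predictive counts.
#' @slot mean per-site posterior-predictive mean.
#' @slot lower,upper per-site 2.5th / 97.5th predictive percentiles.
#' @slot target character label of the forecast target period.
#' @slot model character, `"HBA"` or `"PST"`.
#' @export
setClass("ForecastResult", representation(
    draws = "matrix", mean = "numeric", lower = "numeric", upper = "numeric",
    target = "character", model = "character"))

setValidity("ForecastResult", function(object) {
    d <- object@draws
    if (any(d < 0) || any(d != round(d)))
        "forecast draws must be nonnegative integers" else TRUE
})

#' PSTPosterior: retained draws from the Poisson space-time baseline
#'
#' @slot muCoef draws of spatial-covariate coefficients (coef x draws).
#' @slot alpha array components x periods x draws of latent VAR states.
#' @slot H array components x components x draws of transition matrices.
#' @slot SigmaGamma array of innovation covariance draws.
#' @slot sigma2eps numeric draws of the log-intensity observation variance.
#' @slot basis the fixed spatial basis used (sites x components).
#' @slot Z spatial covariate matrix (sites x coef).
#' @slot acceptRates,seed diagnostics.
#' @export
setClass("PSTPosterior", representation(
    muCoef = "matrix", alpha = "array", H = "array", SigmaGamma = "array",
    sigma2eps = "numeric", basis = "matrix", Z = "matrix",
    acceptRates = "numeric", seed = "integer"))

#' SyntheticScenario: generator settings for synthetic analog-rich data
#'
#' Describes a low-dimensional latent dynamical system (chaotic Lorenz-63 or
#' quasi-periodic torus) observed two ways: a high-dimensional noisy forcing
#' field (a linear spatial projection of the latent state at every sub-period
#' step) and a sparse count field whose per-site Poisson intensity is a
#' softplus link of the latent state at each period's anchored, lagged step.
#' True analogs therefore exist by construction.
#'
#' @slot system `"lorenz"` or `"quasiperiodic"`.
#' @slot nSitesY,nSitesX site counts for the response and forcing fields.
#' @slot nPeriods number of response periods.
#' @slot stepsPerPeriod forcing steps per response period (12 = monthly).
#' @slot spinupSteps extra forcing steps before the first period anchor, so
#'   deep embeddings exist for every period.
#' @slot tau forecast lead in forcing steps.
#' @slot anchorMonth anchor sub-period (month) of each response period.
#' @slot noiseSD forcing observation noise standard deviation.
#' @slot intensityScale multiplier on the count intensities.
#' @slot zeroInflation probability a count is forced to zero.
#' @slot seed integer seed; the scenario is a pure function of its settings.
#' @export
setClass("SyntheticScenario", representation(
    system = "character", nSitesY = "integer", nSitesX = "integer",
    nPeriods = "integer", stepsPerPeriod = "integer", spinupSteps = "integer",
    tau = "integer", anchorMonth = "integer", noiseSD = "numeric",
    intensityScale = "numeric", zeroInflation = "numeric", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
    msg <- NULL
    if (!object@system %in% c("lorenz", "quasiperiodic"))
        msg <- c(msg, "system must be 'lorenz' or 'quasiperiodic'")
    if (object@zeroInflation < 0 || object@zeroInflation >= 1)
        msg <- c(msg, "zeroInflation must be in [0,1)")
    if (is.null(msg)) TRUE else msg
})
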