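# shared builders for small test objects

tinyCounts <- function(seed = 1, ny = 6, nt = 5) {
    set.seed(seed)
    SpaceTimeCounts(matrix(rpois(ny * nt, 4), ny, nt),
                    data.frame(lon = seq(-110, -100, length.out = ny),
                               lat = seq(44, 52, length.out = ny)),
                    2000 + seq_len(nt))
}

tinyForcing <- function(seed = 1, nx = 8, years = 1990:1999) {
    set.seed(seed)
    n <- 12 * length(years)
    ForcingSeries(matrix(rnorm(nx * n), nx, n),
                  data.frame(lon = seq(150, 250, length.out = nx),
                             lat = seq(-20, 40, length.out = nx)),
                  rep(years, each = 12), rep(1:12, length(years)))
}

# coefficient series + anchor alignment small enough for fast cache builds
tinyCoeffs <- function(seed = 1, nAlpha = 3, nSteps = 120) {
    set.seed(seed)
    s <- seq_len(nSteps)
    a <- rbind(sin(2 * pi * s / 19) + 0.4 * sin(4 * pi * s / 19),
               0.6 * cos(2 * pi * s / 19),
               rnorm(nSteps, 0, 0.3))[seq_len(nAlpha), , drop = FALSE]
    new("ForcingCoefficients", coef = a, method = "EOF",
        basis = matrix(0, 0, 0), varianceExplained = numeric(0),
        leNeighbors = NA_integer_, stepYear = integer(0),
        stepMonth = integer(0))
}

# memoised heavy acceptance experiments, shared across acceptance blocks
.acceptanceCache <- new.env(parent = emptyenv())

recoveryRuns <- function() {
    if (!is.null(.acceptanceCache$recovery)) return(.acceptanceCache$recovery)
    out <- lapply(1:10, function(s) {
        fx <- processModelFixture(seed = s)
        cache <- buildDistanceCache(fx$coeffs, fx$alignment, 30:60, 1,
                                    c(target = fx$targetStep))
        fact <- new("NMFFactorization", basis = fx$basis,
                    coef = fx$B[, seq_len(40)],
                    offset = rep(0, nrow(fx$basis)), lossTrace = c(1, 0.5),
                    rank = 5L, init = "custom")
        fit <- hbaFit(fx$counts, fact, cache, HBAHyperParams(),
                      nIter = 5000L, burnIn = 1000L, seed = 100L + s)
        fc <- hbaForecast(fit, cache, fact, 1L, seed = s)
        list(qMode = as.integer(names(which.max(table(fit@q)))),
             theta1Mean = mean(fit@theta1),
             coverage = intervalCoverage(fc, fx$holdout),
             logJoint = fit@logJoint, truth = fx$truth)
    })
    .acceptanceCache$recovery <- out
    out
}
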