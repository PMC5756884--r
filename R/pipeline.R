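# High-level drivers composing the stages: anomalies -> reduction ->
# embedding distances -> MCMC -> forecast, for the analog model and the
# Poisson space-time baseline.

#' Run the full analog forecasting pipeline
#'
#' Convenience driver: computes forcing anomalies over the climatology
#' window, reduces them with EOFs (or Laplacian eigenmaps over a neighbor
#' grid), factorizes the counts with offset NMF, aligns periods with the
#' forcing at lead `tau`, caches Procrustes distances over the q prior
#' support including the forecast target, fits the hierarchical analog model
#' and forecasts the target period.
#'
#' @param counts a [SpaceTimeCounts-class]; all periods are used for
#'   training.
#' @param forcing a [ForcingSeries-class] covering every training anchor at
#'   depth `hyper@qMax` and the target anchor.
#' @param targetPeriod label of the forecast target (its anchor month must
#'   exist in the forcing labels).
#' @param climWindow integer years for the monthly climatology.
#' @param tau forecast lead in forcing steps (default 12).
#' @param anchorMonth anchor sub-period (default 5, May).
#' @param nBasis NMF rank (reference analysis: 14).
#' @param nAlpha number of forcing components (reference analysis: 16).
#' @param method `"eof"` or `"le"`.
#' @param leGrid neighbor grid for `method = "le"` (default `6 + 3 * 0:10`).
#' @param hyper an [HBAHyperParams-class].
#' @param nIter,burnIn,seed MCMC settings.
#' @param sampleB sample the coefficient matrix (see [hbaFit()]).
#' @return list with elements `forecast` ([ForecastResult-class]), `fit`
#'   ([HBAPosterior-class]), `factorization`, `coeffs`, `cache`,
#'   `alignment`.
#' @export
hbaAnalysis <- function(counts, forcing, targetPeriod, climWindow,
                        tau = 12L, anchorMonth = 5L, nBasis = 14L,
                        nAlpha = 16L, method = c("eof", "le"),
                        leGrid = 6L + 3L * (0:10), hyper = HBAHyperParams(),
                        nIter = 20000L, burnIn = 2000L, seed = 1L,
                        sampleB = FALSE) {
    method <- match.arg(method)
    anom <- computeAnomalies(forcing, climWindow)
    coeffs <- if (method == "eof") eofCoefficients(anom, nAlpha)
              else lapply(leGrid, function(k)
                  laplacianEigenmapCoefficients(anom, nAlpha, k))
    alignment <- alignPeriods(counts, forcing, tau, anchorMonth, hyper@qMax,
                              climWindow)
    lab <- stepLabels(forcing)
    tStep <- which(lab$year == targetPeriod & lab$month == anchorMonth)
    if (length(tStep) != 1L)
        stop("target period ", targetPeriod, " has no anchor step")
    targetSteps <- setNames(as.integer(tStep - tau), targetPeriod)
    cache <- buildDistanceCache(coeffs, alignment,
                                hyper@qMin:hyper@qMax, hyper@theta2,
                                targetSteps)
    fact <- fitOffsetNMF(counts(counts), nBasis)
    fit <- hbaFit(counts, fact, cache, hyper, nIter, burnIn, seed,
                  sampleB = sampleB)
    fc <- hbaForecast(fit, cache, fact, target = 1L, seed = seed)
    fc@target <- as.character(targetPeriod)
    list(forecast = fc, fit = fit, factorization = fact, coeffs = coeffs,
         cache = cache, alignment = alignment)
}

#' Run the Poisson space-time baseline pipeline
#'
#' Kernel-PCA scores of the `log1p` count field provide the fixed spatial
#' basis; [pstFit()] and [pstForecast()] do the rest.
#'
#' @param counts a [SpaceTimeCounts-class].
#' @param nComponents latent VAR dimension (defaults to the analog model's
#'   NMF rank in comparative experiments).
#' @param nIter,burnIn,seed MCMC settings.
#' @param targetPeriod label for the forecast output.
#' @return list with `forecast` and `fit`.
#' @export
pstAnalysis <- function(counts, nComponents, nIter = 3000L, burnIn = 500L,
                        seed = 1L, targetPeriod = "T+1") {
    kp <- kpcaCoefficients(log1p(counts(counts)), nComponents)
    fit <- pstFit(counts, basisMatrix(kp), siteCoords(counts),
                  nIter = nIter, burnIn = burnIn, seed = seed)
    fc <- pstForecast(fit, seed = seed, target = as.character(targetPeriod))
    list(forecast = fc, fit = fit)
}
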