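#' @importFrom BiocGenerics counts
NULL

#' Accessors for analogcast containers
#'
#' `counts()` returns the count matrix of a [SpaceTimeCounts-class];
#' `forcingValues()` the value matrix of a [ForcingSeries-class];
#' `siteCoords()` the lon/lat table of either; `periodLabels()` /
#' `stepLabels()` the time labels; `basisMatrix()`, `coefMatrix()` and
#' `offsetVector()` the pieces of an [NMFFactorization-class] or
#' [ForcingCoefficients-class]; `lossTrace()` the NMF objective trace.
#'
#' @param object an analogcast container.
#' @param ... unused.
#' @return the extracted component (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "SpaceTimeCounts", function(object, ...)
    assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("forcingValues", function(object) standardGeneric("forcingValues"))

#' @rdname accessors
#' @export
setMethod("forcingValues", "ForcingSeries", function(object)
    assay(object, "values"))

#' @rdname accessors
#' @export
setGeneric("siteCoords", function(object) standardGeneric("siteCoords"))

#' @rdname accessors
#' @export
setMethod("siteCoords", "SummarizedExperiment", function(object)
    as.data.frame(rowData(object)[, c("lon", "lat")]))

#' @rdname accessors
#' @export
setGeneric("periodLabels", function(object) standardGeneric("periodLabels"))

#' @rdname accessors
#' @export
setMethod("periodLabels", "SpaceTimeCounts", function(object)
    colData(object)$period)

#' @rdname accessors
#' @export
setGeneric("stepLabels", function(object) standardGeneric("stepLabels"))

#' @rdname accessors
#' @export
setMethod("stepLabels", "ForcingSeries", function(object)
    data.frame(year = colData(object)$year, month = colData(object)$month))

#' @rdname accessors
#' @export
setMethod("stepLabels", "ForcingCoefficients", function(object)
    data.frame(year = object@stepYear, month = object@stepMonth))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setMethod("basisMatrix", "NMFFactorization", function(object) object@basis)

#' @rdname accessors
#' @export
setMethod("basisMatrix", "ForcingCoefficients", function(object) object@basis)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))

#' @rdname accessors
#' @export
setMethod("coefMatrix", "NMFFactorization", function(object) object@coef)

#' @rdname accessors
#' @export
setMethod("coefMatrix", "ForcingCoefficients", function(object) object@coef)

#' @rdname accessors
#' @export
setGeneric("offsetVector", function(object) standardGeneric("offsetVector"))

#' @rdname accessors
#' @export
setMethod("offsetVector", "NMFFactorization", function(object) object@offset)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @rdname accessors
#' @export
setMethod("lossTrace", "NMFFactorization", function(object) object@lossTrace)

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(object)
    standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setMethod("varianceExplained", "ForcingCoefficients", function(object)
    object@varianceExplained)

setMethod("show", "NMFFactorization", function(object) {
    cat(sprintf("NMFFactorization: %d sites x %d periods, rank %d (%s init)\n",
                nrow(object@basis), ncol(object@coef), object@rank,
                object@init))
    cat(sprintf("  offset: %s; final loss %.6g after %d iterations\n",
                if (all(object@offset == 0)) "off" else "on",
                utils::tail(object@lossTrace, 1L),
                length(object@lossTrace)))
})

setMethod("show", "ForcingCoefficients", function(object) {
    cat(sprintf("ForcingCoefficients (%s): %d components x %d steps\n",
                object@method, nrow(object@coef), ncol(object@coef)))
    if (length(object@varianceExplained))
        cat(sprintf("  variance explained: %s\n",
                    paste(sprintf("%.3f", object@varianceExplained),
                          collapse = " ")))
})

setMethod("show", "DistanceCache", function(object) {
    cat(sprintf(
        "DistanceCache: pool of %d periods, q in [%d, %d], theta2 = %g\n",
        length(object@pool), min(object@qRange), max(object@qRange),
        object@theta2))
    if (length(object@leGrid))
        cat(sprintf("  LE neighbor grid: %s\n",
                    paste(object@leGrid, collapse = " ")))
    if (length(object@targets))
        cat(sprintf("  forecast targets: %s\n",
                    paste(object@targets, collapse = " ")))
})

setMethod("show", "HBAPosterior", function(object) {
    cat(sprintf("HBAPosterior: %d retained draws (seed %d)\n",
                length(object@q), object@seed))
    cat(sprintf("  q: mode %d | m: mode %d | theta1: mean %.4g | sigma2eta: mean %.4g\n",
                as.integer(names(which.max(table(object@q)))),
                as.integer(names(which.max(table(object@m)))),
                mean(object@theta1), mean(object@sigma2eta)))
    cat("  acceptance rates:",
        paste(sprintf("%s=%.2f", names(object@acceptRates),
                      object@acceptRates), collapse = " "), "\n")
})

setMethod("show", "ForecastResult", function(object) {
    cat(sprintf("ForecastResult (%s) for %s: %d sites, %d draws\n",
                object@model, object@target, nrow(object@draws),
                ncol(object@draws)))
    cat(sprintf("  predictive mean in [%.2f, %.2f]\n",
                min(object@mean), max(object@mean)))
})

setMethod("show", "SyntheticScenario", function(object) {
    cat(sprintf(
        "SyntheticScenario '%s': %d response sites x %d periods, %d forcing sites\n",
        object@system, object@nSitesY, object@nPeriods, object@nSitesX))
    cat(sprintf("  %d steps/period, tau = %d, seed = %d\n",
                object@stepsPerPeriod, object@tau, object@seed))
})
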