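# Forecast scoring: mean squared prediction error, correlation of predictive
# means with observations across sites, and central-interval coverage.

#' Mean squared prediction error
#'
#' Mean over sites of the squared difference between posterior-predictive
#' means and observed counts. Invariant to site ordering (applied jointly).
#'
#' @param predMean per-site predictive means, or a [ForecastResult-class].
#' @param observed per-site observed counts.
#' @return a nonnegative scalar.
#' @export
mspe <- function(predMean, observed) {
    if (is(predMean, "ForecastResult")) predMean <- predMean@mean
    if (length(predMean) != length(observed))
        stop("prediction and observation lengths differ")
    mean((predMean - observed)^2)
}

#' Correlation of forecasts with observations
#'
#' Pearson correlation across sites between predictive means and observed
#' counts for a single forecast period. Zero variance on either side is a
#' reported error, not a silent `NA`.
#'
#' @param predMean per-site predictive means, or a [ForecastResult-class].
#' @param observed per-site observed counts.
#' @return correlation in `[-1, 1]`.
#' @export
predictionCorrelation <- function(predMean, observed) {
    if (is(predMean, "ForecastResult")) predMean <- predMean@mean
    if (length(predMean) != length(observed))
        stop("prediction and observation lengths differ")
    if (sd(predMean) == 0 || sd(observed) == 0)
        stop("zero variance: correlation undefined")
    cor(predMean, observed)
}

#' Central predictive-interval coverage
#'
#' Fraction of sites whose observed count lies inside the central interval of
#' the predictive draws (linear-interpolation empirical quantiles).
#'
#' @param draws sites x draws matrix of predictive counts, or a
#'   [ForecastResult-class].
#' @param observed per-site observed counts.
#' @param level interval mass (default 0.95).
#' @return coverage fraction in `[0, 1]`.
#' @export
intervalCoverage <- function(draws, observed, level = 0.95) {
    if (is(draws, "ForecastResult")) draws <- draws@draws
    if (ncol(draws) < 100L) stop("need at least 100 draws per site")
    a <- (1 - level) / 2
    lo <- apply(draws, 1L, quantile, probs = a, names = FALSE)
    hi <- apply(draws, 1L, quantile, probs = 1 - a, names = FALSE)
    mean(observed >= lo & observed <= hi)
}

#' Score a forecast against observations
#'
#' @param forecast a [ForecastResult-class].
#' @param observed per-site observed counts.
#' @return data.frame with columns `model`, `target`, `mspe`, `correlation`,
#'   `coverage95`.
#' @export
scoreForecast <- function(forecast, observed) {
    data.frame(model = forecast@model, target = forecast@target,
               mspe = mspe(forecast@mean, observed),
               correlation = predictionCorrelation(forecast@mean, observed),
               coverage95 = intervalCoverage(forecast@draws, observed))
}
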