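# Reading/writing the long tabular formats, climatological anomalies, and the
# response-period <-> forcing-step alignment.

#' Construct a SpaceTimeCounts object
#'
#' @param counts nonnegative integer matrix, sites x periods.
#' @param siteCoords data.frame with columns `lon`, `lat` (one row per site).
#'   Coordinates are carried for mapping and output only; no computation in
#'   the model uses them.
#' @param periodLabels strictly increasing integer period labels (e.g. survey
#'   years).
#' @return a [SpaceTimeCounts-class].
#' @examples
#' y <- matrix(rpois(15, 3), 5, 3)
#' stc <- SpaceTimeCounts(y, data.frame(lon = 1:5, lat = 1:5), 2001:2003)
#' counts(stc)
#' @export
SpaceTimeCounts <- function(counts, siteCoords, periodLabels) {
    counts <- as.matrix(counts)
    if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
        stop("counts must be nonnegative integers with no NA")
    storage.mode(counts) <- "integer"
    colnames(counts) <- periodLabels
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(lon = siteCoords$lon, lat = siteCoords$lat,
                            row.names = rownames(counts)),
        colData = DataFrame(period = as.integer(periodLabels)))
    new("SpaceTimeCounts", se)
}

#' Construct a ForcingSeries object
#'
#' @param values finite numeric matrix, sites x steps.
#' @param siteCoords data.frame with columns `lon`, `lat`.
#' @param stepYear,stepMonth integer labels per step; steps must be strictly
#'   increasing and equally spaced in months.
#' @return a [ForcingSeries-class].
#' @export
ForcingSeries <- function(values, siteCoords, stepYear, stepMonth) {
    values <- as.matrix(values)
    se <- SummarizedExperiment(
        assays = list(values = values),
        rowData = DataFrame(lon = siteCoords$lon, lat = siteCoords$lat,
                            row.names = rownames(values)),
        colData = DataFrame(year = as.integer(stepYear),
                            month = as.integer(stepMonth)))
    new("ForcingSeries", se)
}

#' Read a long-format count table
#'
#' Expects a CSV with header `site_id,lon,lat,period,count`, one row per
#' (site, period) observation. Sites are sorted by id and periods ascending;
#' the dense site x period matrix is assembled without imputation, so every
#' (site, period) cell must be present exactly once.
#'
#' @param path path to the CSV file.
#' @return a [SpaceTimeCounts-class].
#' @export
readCounts <- function(path) {
    stopifnot(file.exists(path))
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("site_id", "lon", "lat", "period", "count")
    if (!all(need %in% names(d)))
        stop("count file must have columns ", paste(need, collapse = ","))
    bad <- which(d$count < 0 | d$count != round(d$count))
    if (length(bad))
        stop("negative or non-integer count at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
    key <- paste(d$site_id, d$period, sep = "/")
    if (anyDuplicated(key))
        stop("duplicate (site, period) rows: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    sites <- sort(unique(d$site_id))
    periods <- sort(unique(d$period))
    full <- expand.grid(site_id = sites, period = periods)
    if (nrow(d) != nrow(full))
        stop("missing (site, period) cells; periods with no observation must ",
             "be absent for every site, not imputed")
    y <- matrix(NA_integer_, length(sites), length(periods),
                dimnames = list(sites, periods))
    y[cbind(match(d$site_id, sites), match(d$period, periods))] <- d$count
    coords <- d[!duplicated(d$site_id), c("site_id", "lon", "lat")]
    coords <- coords[match(sites, coords$site_id), ]
    SpaceTimeCounts(y, coords, periods)
}

#' Write counts as a long-format CSV
#'
#' Inverse of [readCounts()]: a read-write-read round trip reproduces the
#' count matrix exactly.
#'
#' @param object a [SpaceTimeCounts-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(object, path) {
    y <- counts(object)
    co <- siteCoords(object)
    sid <- if (is.null(rownames(y))) seq_len(nrow(y)) else rownames(y)
    d <- data.frame(
        site_id = rep(sid, times = ncol(y)),
        lon = rep(co$lon, times = ncol(y)),
        lat = rep(co$lat, times = ncol(y)),
        period = rep(periodLabels(object), each = nrow(y)),
        count = as.vector(y))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a long-format forcing table
#'
#' Expects a CSV with header `site_id,lon,lat,year,month,value`. Every
#' (site, step) cell must be present and finite: missing forcing cells are an
#' error, not interpolated, because imputation distorts analog distances.
#'
#' @param path path to the CSV file.
#' @return a [ForcingSeries-class].
#' @export
readForcing <- function(path) {
    stopifnot(file.exists(path))
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("site_id", "lon", "lat", "year", "month", "value")
    if (!all(need %in% names(d)))
        stop("forcing file must have columns ", paste(need, collapse = ","))
    if (any(!is.finite(d$value)))
        stop("non-finite forcing values are not allowed")
    sites <- sort(unique(d$site_id))
    stepIdx <- 12L * d$year + (d$month - 1L)
    steps <- sort(unique(stepIdx))
    x <- matrix(NA_real_, length(sites), length(steps),
                dimnames = list(sites, NULL))
    x[cbind(match(d$site_id, sites), match(stepIdx, steps))] <- d$value
    if (anyNA(x))
        stop("missing (site, step) forcing cells are not allowed")
    coords <- d[!duplicated(d$site_id), c("site_id", "lon", "lat")]
    coords <- coords[match(sites, coords$site_id), ]
    ForcingSeries(x, coords, steps %/% 12L, steps %% 12L + 1L)
}

#' Climatological anomalies of a forcing field
#'
#' Subtracts, per site and sub-period (month), the mean of that site's values
#' for that month over the climatology window. The operator is idempotent for
#' a fixed window: a second application changes nothing, because the window
#' means of the first pass's output are zero.
#'
#' @param forcing a [ForcingSeries-class].
#' @param window integer vector of years forming the climatology window
#'   (e.g. `1970:1999`). A required choice, never inferred from the data.
#' @return a [ForcingSeries-class] of anomalies, same shape.
#' @export
computeAnomalies <- function(forcing, window) {
    lab <- stepLabels(forcing)
    x <- forcingValues(forcing)
    months <- sort(unique(lab$month))
    out <- x
    for (mo in months) {
        inWin <- which(lab$month == mo & lab$year %in% window)
        if (length(inWin) == 0L)
            stop("month ", mo, " has no steps inside the climatology window")
        if (length(inWin) < 2L)
            stop("month ", mo, " occurs fewer than twice in the window")
        colsMo <- which(lab$month == mo)
        clim <- rowMeans(x[, inWin, drop = FALSE])
        out[, colsMo] <- x[, colsMo, drop = FALSE] - clim
    }
    ForcingSeries(out, siteCoords(forcing), lab$year, lab$month)
}

#' Align response periods with forcing steps
#'
#' Maps each response period t to the forcing step that anchors its embedding
#' matrix: the step of the anchor sub-period (e.g. May) in period t, minus the
#' lead `tau` in forcing steps. With monthly forcing, a May anchor and
#' `tau = 12`, a target period of 2014 is anchored at May 2013, giving a
#' one-year-ahead forecast. Periods whose anchored step lacks `qMax - 1`
#' earlier steps are flagged so downstream pool construction can exclude them.
#' The mapping is a pure function of the labels: input row order is
#' irrelevant.
#'
#' @param counts a [SpaceTimeCounts-class] (periods are its labels).
#' @param forcing a [ForcingSeries-class].
#' @param tau nonnegative integer lead, in forcing steps (12 = one year ahead
#'   for monthly forcing).
#' @param anchorMonth integer month anchoring each period.
#' @param qMax deepest embedding the alignment must support.
#' @param climWindow optional integer years recorded alongside the alignment.
#' @return an [AlignmentSpec-class].
#' @export
alignPeriods <- function(counts, forcing, tau, anchorMonth, qMax,
                         climWindow = integer(0)) {
    stopifnot(tau >= 0)
    lab <- stepLabels(forcing)
    periods <- periodLabels(counts)
    anchor <- vapply(periods, function(p) {
        i <- which(lab$year == p & lab$month == anchorMonth)
        if (length(i) != 1L)
            stop("anchor month ", anchorMonth, " not present for period ", p)
        i
    }, integer(1)) - as.integer(tau)
    if (any(anchor < 1L))
        stop("tau = ", tau, " pushes period(s) ",
             paste(periods[anchor < 1L], collapse = ", "),
             " before the first forcing step")
    flagged <- anchor - (as.integer(qMax) - 1L) < 1L
    new("AlignmentSpec", tau = as.integer(tau),
        anchorMonth = as.integer(anchorMonth),
        periodToStep = setNames(anchor, periods), flagged = flagged,
        climWindow = as.integer(climWindow))
}
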