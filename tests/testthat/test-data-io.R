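# long-format I/O, climatological anomalies, period-step alignment

test_that("readCounts assembles a sorted dense matrix and validates input", {
    f <- tempfile(fileext = ".csv")
    d <- data.frame(site_id = c(2, 2, 2, 1, 1, 1),
                    lon = c(-101, -101, -101, -100, -100, -100),
                    lat = c(45, 45, 45, 44, 44, 44),
                    period = c(1999, 1998, 2000, 2000, 1999, 1998),
                    count = c(4, 3, 5, 2, 1, 0))
    write.csv(d, f, row.names = FALSE)
    x <- readCounts(f)
    expect_equal(dim(counts(x)), c(2L, 3L))
    expect_equal(unname(counts(x)[1, ]), c(0L, 1L, 2L))   # site 1 sorted
    expect_equal(periodLabels(x), 1998:2000)

    d2 <- d; d2$count[1] <- -1
    write.csv(d2, f, row.names = FALSE)
    expect_error(readCounts(f), "row")
    d3 <- rbind(d, d[4, ])
    write.csv(d3, f, row.names = FALSE)
    expect_error(readCounts(f), "duplicate")
})

test_that("counts round-trip read -> write -> read exactly", {
    x <- tinyCounts(3)
    f <- tempfile(fileext = ".csv")
    writeCounts(x, f)
    y <- readCounts(f)
    expect_identical(unname(counts(y)), unname(counts(x)))
    expect_equal(periodLabels(y), periodLabels(x))
})

test_that("anomalies subtract site-month climatology and are idempotent", {
    fr <- tinyForcing(1)
    # constant series -> zero anomalies
    cst <- ForcingSeries(matrix(7, 3, 24), data.frame(lon = 1:3, lat = 1:3),
                         rep(1990:1991, each = 12), rep(1:12, 2))
    expect_true(all(forcingValues(computeAnomalies(cst, 1990:1991)) == 0))
    # one site, January values 1 and 3 in window, later January value 4
    v <- matrix(0, 1, 36)
    v[1, c(1, 13, 25)] <- c(1, 3, 4)
    one <- ForcingSeries(v, data.frame(lon = 0, lat = 0),
                         rep(1990:1992, each = 12), rep(1:12, 3))
    an <- computeAnomalies(one, 1990:1991)
    expect_equal(forcingValues(an)[1, 25], 2)
    # idempotence under a fixed window
    a1 <- computeAnomalies(fr, 1990:1999)
    a2 <- computeAnomalies(a1, 1990:1999)
    expect_equal(forcingValues(a2), forcingValues(a1), tolerance = 1e-12)
    # degenerate window
    expect_error(computeAnomalies(fr, 2050:2060), "window")
})

test_that("alignment maps the anchor month minus tau and flags history", {
    ny <- 3
    counts <- SpaceTimeCounts(matrix(0:8, ny, 3),
                              data.frame(lon = 1:ny, lat = 1:ny),
                              c(1971, 1990, 2014))
    fr <- tinyForcing(1, nx = 2, years = 1970:2014)
    al <- alignPeriods(counts, fr, tau = 12, anchorMonth = 5, qMax = 60)
    lab <- stepLabels(fr)
    s2014 <- al@periodToStep[["2014"]]
    expect_equal(lab$year[s2014], 2013)     # one-year-ahead: May 2013 anchor
    expect_equal(lab$month[s2014], 5)
    # tau = 0 anchors in the target period itself
    al0 <- alignPeriods(counts, fr, tau = 0, anchorMonth = 5, qMax = 60)
    expect_equal(lab$year[al0@periodToStep[["1990"]]], 1990)
    # early period lacks deep-embedding history
    expect_true(al@flagged[[1]])
    expect_false(al@flagged[[3]])
    # pure function of labels: permuting forcing site rows changes nothing
    perm <- ForcingSeries(forcingValues(fr)[2:1, ],
                          siteCoords(fr)[2:1, ], lab$year, lab$month)
    alp <- alignPeriods(counts, perm, tau = 12, anchorMonth = 5, qMax = 60)
    expect_identical(alp@periodToStep, al@periodToStep)
})

test_that("container validity rejects malformed inputs", {
    expect_error(SpaceTimeCounts(matrix(-1, 3, 3),
                                 data.frame(lon = 1:3, lat = 1:3), 1:3))
    expect_error(SpaceTimeCounts(matrix(1.5, 3, 3),
                                 data.frame(lon = 1:3, lat = 1:3), 1:3))
    expect_error(ForcingSeries(matrix(NA_real_, 2, 2),
                               data.frame(lon = 1:2, lat = 1:2),
                               c(1990, 1990), c(1, 2)))
})
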