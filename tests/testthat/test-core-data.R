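test_that("connectome CSV round-trips and validates", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("0,0,0", "0,0,0", "0,0,0"), f)
    sc <- readConnectome(f)
    expect_s4_class(sc, "StructuralConnectome")
    expect_true(all(weights(sc) == 0))
    expect_false(isDirected(sc))

    # asymmetry forces directed = TRUE
    m <- matrix(0, 4, 4)
    m[1, 2] <- 5
    write.table(m, f, sep = ",", row.names = FALSE, col.names = FALSE)
    expect_true(isDirected(readConnectome(f)))

    # full-precision round trip
    set.seed(7)
    w <- matrix(rnorm(100), 10)
    diag(w) <- 0
    sc <- StructuralConnectome(w, directed = TRUE)
    lf <- withr::local_tempfile(fileext = ".txt")
    writeConnectome(sc, f, labelsPath = lf)
    back <- readConnectome(f, labelsPath = lf)
    expect_equal(weights(back), weights(sc), tolerance = 1e-12)
    expect_identical(regionLabels(back), regionLabels(sc))
})

test_that("connectome reader rejects malformed input and cleans diagonals", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("0,1,2", "1,0,3"), f)
    expect_error(readConnectome(f), "square")
    writeLines(c("0,1", "a,0"), f)
    expect_error(readConnectome(f))
    writeLines(c("2,1", "1,2"), f)
    expect_message(sc <- readConnectome(f), "diagonal")
    expect_equal(unname(diag(weights(sc))), c(0, 0))
    writeLines(c("0,1", "1,0"), f)
    lf <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("A", "B", "C"), lf)
    expect_error(readConnectome(f, labelsPath = lf), "label count")
})

test_that("symmetrization averages weight pairs and is idempotent", {
    m <- matrix(0, 3, 3)
    m[1, 2] <- 2
    sc <- StructuralConnectome(m, directed = TRUE)
    sym <- symmetrizeConnectome(sc)
    expect_equal(weights(sym)[1, 2], 1)
    expect_equal(weights(sym)[2, 1], 1)
    expect_false(isDirected(sym))

    set.seed(1)
    w <- matrix(runif(400), 20)
    diag(w) <- 0
    sym <- symmetrizeConnectome(StructuralConnectome(w, directed = TRUE))
    expect_lt(max(abs(weights(sym) - t(weights(sym)))), 1e-12)
    # fixed point on already-symmetric input
    expect_equal(weights(symmetrizeConnectome(sym)), weights(sym))
})

test_that("density thresholding keeps the strongest edge slots", {
    w <- matrix(0, 4, 4)
    w[1, 2] <- 6; w[1, 3] <- 5; w[2, 3] <- 4; w[1, 4] <- 3; w[2, 4] <- 2
    w[3, 4] <- 1
    w <- w + t(w)
    sc <- StructuralConnectome(w)
    thr <- thresholdDensity(sc, 0.5)
    kept <- weights(thr)[upper.tri(w)]
    expect_setequal(kept[kept != 0], c(6, 5, 4))

    expect_equal(weights(thresholdDensity(sc, 1)), weights(sc))

    set.seed(3)
    w <- matrix(rnorm(900), 30)
    w <- w + t(w); diag(w) <- 0
    thr <- thresholdDensity(StructuralConnectome(w), 0.5)
    expect_equal(sum(weights(thr)[upper.tri(w)] != 0), ceiling(0.5 * 435))
    # idempotent at the same density, and symmetric removal
    expect_equal(weights(thresholdDensity(thr, 0.5)), weights(thr))
    expect_lt(max(abs(weights(thr) - t(weights(thr)))), 1e-15)

    expect_error(thresholdDensity(sc, 0), "density")
    expect_error(thresholdDensity(sc, 1.2), "density")
})

test_that("coupling rescaling pins the maximum absolute weight", {
    w <- matrix(c(0, 10, 10, 0), 2)
    sc <- scaleCoupling(StructuralConnectome(w), 0.2)
    expect_equal(weights(sc)[1, 2], 0.2)
    expect_equal(weights(sc), w * 0.02, ignore_attr = TRUE)
    set.seed(4)
    w <- matrix(rnorm(100), 10); w <- w + t(w); diag(w) <- 0
    out <- scaleCoupling(StructuralConnectome(w), 0.2)
    expect_equal(max(abs(weights(out))), 0.2, tolerance = 1e-12)
    # already at target: unchanged
    expect_equal(weights(scaleCoupling(out, 0.2)), weights(out))
    expect_error(scaleCoupling(StructuralConnectome(matrix(0, 2, 2))),
                 "all-zero")
})

test_that("band-pass keeps the passband, kills the stopband and DC", {
    t <- seq(0, 720, by = 0.72)
    mid <- 200:800
    inband <- RegionalTimeSeries(cbind(sin(2 * pi * 0.05 * t)), 0.72)
    out <- bandpassFilter(inband, 0.008, 0.09)
    expect_equal(bandHz(out), c(0.008, 0.09))
    expect_gt(max(abs(signalMatrix(out)[mid, 1])), 0.95)

    fast <- RegionalTimeSeries(cbind(sin(2 * pi * 0.3 * t)), 0.72)
    out <- bandpassFilter(fast, 0.008, 0.09)
    expect_lt(max(abs(signalMatrix(out)[mid, 1])), 0.1)

    flat <- RegionalTimeSeries(cbind(rep(2, length(t))), 0.72)
    expect_lt(max(abs(signalMatrix(bandpassFilter(flat, 0.008, 0.09)))),
              1e-10)

    expect_error(bandpassFilter(inband, 0.01, 0.9), "Nyquist")
})

test_that("band-pass commutes with column permutation", {
    set.seed(5)
    v <- matrix(rnorm(300 * 4), 300, 4)
    ts <- RegionalTimeSeries(v, 1)
    perm <- c(3, 1, 4, 2)
    a <- signalMatrix(bandpassFilter(RegionalTimeSeries(v[, perm], 1),
                                     0.01, 0.1))
    b <- signalMatrix(bandpassFilter(ts, 0.01, 0.1))[, perm]
    expect_equal(unname(a), unname(b))
})

test_that("time-series TSV and YAML sidecar round-trip", {
    set.seed(6)
    ts <- RegionalTimeSeries(matrix(rnorm(60), 20, 3), trSeconds = 2.6,
                             bandHz = c(0.008, 0.09),
                             labels = c("V1", "M1", "PFC"))
    f <- withr::local_tempfile(fileext = ".tsv")
    mf <- withr::local_tempfile(fileext = ".yaml")
    writeTimeSeries(ts, f, metaPath = mf)
    back <- readTimeSeries(f, metaPath = mf)
    expect_equal(signalMatrix(back), signalMatrix(ts), tolerance = 1e-12)
    expect_equal(trSeconds(back), 2.6)
    expect_equal(bandHz(back), c(0.008, 0.09))
    expect_identical(regionLabels(back), c("V1", "M1", "PFC"))
    expect_error(readTimeSeries(f), "sampling period")
})

test_that("class validity catches inconsistent objects", {
    expect_error(StructuralConnectome(matrix(1:6, 2, 3)), "square")
    w <- matrix(c(0, 1, 2, 0), 2)
    expect_error(StructuralConnectome(w, directed = FALSE), "symmetric")
    expect_error(RegionalTimeSeries(matrix(1, 1, 2), 1), "2 time points")
    expect_error(RegionalTimeSeries(matrix(c(1, NA, 2, 3), 2), 1), "finite")
    expect_error(HopfParameters(n = 2, dt = 0.5, trSeconds = 0.3), "dt")
})
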