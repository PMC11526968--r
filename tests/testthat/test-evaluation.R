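test_that("FC fit correlation behaves on identities and random input", {
    a <- random_corr(6, 31)
    expect_equal(fcFit(a, a), 1)
    neg <- -a; diag(neg) <- 1
    expect_equal(fcFit(a, neg), -1)
    b <- random_corr(6, 32)
    ut <- upper.tri(a)
    expect_equal(fcFit(a, b), cor(a[ut], b[ut]))
    expect_error(fcFit(a, random_corr(5, 1)), "shape")
    expect_error(fcFit(diag(3), diag(3)), "zero-variance")
})

test_that("SSIM decomposes into luminance, contrast and structure", {
    a <- random_corr(8, 33)
    expect_equal(fcSSIM(a, a), 1)

    shifted <- a + 0.3
    L <- max(c(a, shifted)) - min(c(a, shifted))
    c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
    x <- as.numeric(a); y <- as.numeric(shifted)
    lum <- (2 * mean(x) * mean(y) + c1) / (mean(x)^2 + mean(y)^2 + c1)
    n <- length(x)
    vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
    sxy <- mean((x - mean(x)) * (y - mean(y)))
    contrast <- (2 * sqrt(vx) * sqrt(vy) + c2) / (vx + vy + c2)
    structure_ <- (sxy + c2 / 2) / (sqrt(vx) * sqrt(vy) + c2 / 2)
    # mean shift: luminance < 1, structure = 1, product reproduces fcSSIM
    expect_lt(lum, 1)
    expect_equal(structure_, 1, tolerance = 1e-12)
    expect_equal(fcSSIM(a, shifted), lum * contrast * structure_,
                 tolerance = 1e-12)

    b <- random_corr(8, 34)
    xb <- as.numeric(b)
    vxb <- mean((xb - mean(xb))^2)
    sxyb <- mean((x - mean(x)) * (xb - mean(xb)))
    Lb <- max(c(x, xb)) - min(c(x, xb))
    ref <- ((2 * mean(x) * mean(xb) + (0.01 * Lb)^2) * (2 * sxyb +
        (0.03 * Lb)^2)) / ((mean(x)^2 + mean(xb)^2 + (0.01 * Lb)^2) *
        (vx + vxb + (0.03 * Lb)^2))
    expect_equal(fcSSIM(a, b), ref, tolerance = 1e-12)
    const <- matrix(0.5, 8, 8)
    expect_error(fcSSIM(const, const), "range")
})

test_that("differential identifiability separates subjects", {
    fcs <- lapply(1:3, function(k) random_corr(7, 40 + k))
    id <- identifiability(fcs, fcs)
    expect_equal(id$iSelf, 1)
    expect_gt(id$iDiff, 0)
    # hand-computed oracle on the 3-subject fixture
    ut <- upper.tri(fcs[[1]])
    A <- matrix(NA, 3, 3)
    for (i in 1:3) for (j in 1:3)
        A[i, j] <- cor(fcs[[i]][ut], fcs[[j]][ut])
    expect_equal(id$similarity, A)
    expect_equal(id$iDiff, mean(diag(A)) - mean(A[row(A) != col(A)]))

    same <- identifiability(list(fcs[[1]], fcs[[1]]),
                            list(fcs[[1]], fcs[[1]]))
    expect_equal(same$iDiff, 0)
    expect_error(identifiability(fcs[1], fcs[1]), "2 subjects")

    # invariant under a common region permutation
    perm <- c(3, 1, 2, 7, 5, 6, 4)
    pfcs <- lapply(fcs, function(m) m[perm, perm])
    expect_equal(identifiability(pfcs, pfcs)$iDiff, id$iDiff)
})

test_that("cognitive matching scores the best positive map correlation", {
    set.seed(51)
    n <- 30; k <- 5
    maps <- matrix(rnorm(n * k), n, k)
    ts <- RegionalTimeSeries(matrix(rep(maps[, 3], 10), 10, n, byrow = TRUE) +
                             matrix(rnorm(10 * n, sd = 1e-8), 10, n), 1)
    cm <- cognitiveMatching(ts, maps)
    expect_equal(cm$scanScore, 1, tolerance = 1e-6)
    expect_true(all(cm$bestMap == 3))

    # activity orthogonal to every map scores 0 (floor rule)
    act <- rnorm(n)
    q <- qr.Q(qr(cbind(maps, 1)))
    orth <- act - q %*% crossprod(q, act)
    ts0 <- RegionalTimeSeries(rbind(orth[, 1], orth[, 1]), 1)
    maps1 <- maps[, 1, drop = FALSE]
    r <- cor(orth[, 1], maps1[, 1])
    cm0 <- cognitiveMatching(ts0, maps1)
    expect_equal(cm0$scanScore, max(0, r), tolerance = 1e-10)

    # brute-force max-of-correlations oracle
    v <- matrix(rnorm(20 * n), 20, n)
    tsr <- RegionalTimeSeries(v, 1)
    cmr <- cognitiveMatching(tsr, maps)
    oracle <- mean(apply(v, 1, function(row) max(0, max(cor(row, maps)))))
    expect_equal(cmr$scanScore, oracle, tolerance = 1e-12)

    # invariant under affine rescaling of any map
    maps2 <- maps
    maps2[, 2] <- 5 * maps2[, 2] + 3
    expect_equal(cognitiveMatching(tsr, maps2)$perVolume, cmr$perVolume)
    expect_error(cognitiveMatching(tsr, maps[1:10, ]), "align")
})

test_that("sign-flip paired test matches the exhaustive oracle", {
    set.seed(61)
    a <- rnorm(10, mean = 0.4)
    b <- rnorm(10)
    pc <- pairedComparison(a, b, nResamples = 20000, seed = 5)
    d <- a - b
    tObs <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(pc$tStatistic, tObs)
    # exhaustive enumeration of all 2^10 sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
    tAll <- apply(signs, 1, function(s) {
        ds <- s * d
        mean(ds) / (sd(ds) / sqrt(10))
    })
    pExact <- mean(abs(tAll) >= abs(tObs) - 1e-12)
    expect_equal(pc$pResampled, pExact,
                 tolerance = 4 * sqrt(pExact * (1 - pExact) / 20000) /
                     max(pExact, 1e-6))
    # Hedges g by the hand formula
    sPooled <- sqrt((9 * var(a) + 9 * var(b)) / 18)
    gHand <- (mean(a) - mean(b)) / sPooled * (1 - 3 / (4 * 18 - 1))
    expect_equal(pc$hedgesG, gHand)
})

test_that("degenerate paired comparisons take the documented paths", {
    a <- c(1, 2, 3, 4, 5)
    pc <- pairedComparison(a, a, nResamples = 100, seed = 1)
    expect_equal(pc$pResampled, 1)
    expect_equal(pc$hedgesG, 0)
    expect_equal(pc$tStatistic, 0)

    pc2 <- pairedComparison(a + 1, a, nResamples = 4000, seed = 2)
    # smallest attainable two-sided p at S = 5 is 2/2^5
    expect_equal(pc2$pResampled, 2 / 32, tolerance = 0.15)
    expect_gt(pc2$hedgesG, 0)
    expect_error(pairedComparison(1:2, 2:3), "3 pairs")
})

test_that("the sign-flip p-value is calibrated under the null", {
    set.seed(62)
    ps <- replicate(500, {
        a <- rnorm(8); b <- rnorm(8)
        pairedComparison(a, b, nResamples = 399,
                         seed = sample.int(1e6, 1))$pResampled
    })
    expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.6)  # binomial 3 SE
    expect_lt(abs(mean(ps) - 0.5), 0.05)
    # B = 399 makes p discrete; ties are expected, suppress the KS warning
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})
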