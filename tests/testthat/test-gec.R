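test_that("FC statistics capture lead-lag structure exactly", {
    set.seed(1)
    x <- rnorm(400)
    # column 2 lags column 1 by one sample: cor(x1(t), x2(t+1)) = 1
    v <- cbind(x, c(NA, x[-400]))[-1, ]
    st <- fcStatistics(RegionalTimeSeries(v, 1), lagTRs = 1L)
    expect_equal(st@fcForward[1, 1 + 1], 1, tolerance = 1e-12)
    expect_lt(abs(st@fcForward[2, 1]), 0.2)
    expect_equal(st@fc, t(st@fc), ignore_attr = TRUE)
    expect_equal(unname(diag(st@fc)), c(1, 1))
})

test_that("white noise is statistically reversible", {
    set.seed(2)
    st <- fcStatistics(RegionalTimeSeries(matrix(rnorm(4000 * 4), 4000), 1))
    # sample reversal equals the transposed forward statistic exactly,
    # so irreversibility shows up only through forward-matrix asymmetry
    expect_equal(st@fcReversal, t(st@fcForward), tolerance = 1e-12)
    expect_lt(max(abs(st@fcForward - st@fcReversal)), 6 / sqrt(4000))
})

test_that("fcStatistics flags constant regions and short input", {
    v <- cbind(rnorm(50), rep(1, 50))
    colnames(v) <- c("ok", "flat")
    expect_error(fcStatistics(RegionalTimeSeries(v, 1)), "flat")
    expect_error(fcStatistics(RegionalTimeSeries(matrix(rnorm(6), 3), 1),
                              lagTRs = 1L), "short")
})

test_that("the GEC update follows the two-term gradient rule", {
    fcE <- matrix(c(1, 0.5, 0.5, 1), 2)
    fcS <- matrix(c(1, 0, 0, 1), 2)
    emp <- fc_stub(fcE, fcForward = fcE)
    sim <- fc_stub(fcS, fcForward = fcS)
    g <- matrix(c(0, 0.1, 0.1, 0), 2)
    out <- gecStep(g, emp, sim, epsilon = 2e-4, epsilonPrime = 4e-5)
    expect_equal(out[1, 2], 0.1 + 2e-4 * 0.5)   # lagged bracket cancels

    # clamp rule of the cooperative-only variant
    g2 <- matrix(c(0, 1e-5, 1e-5, 0), 2)
    empB <- fc_stub(matrix(c(1, 0, 0, 1), 2))
    simB <- fc_stub(matrix(c(1, 0.5, 0.5, 1), 2))
    out2 <- gecStep(g2, empB, simB, allowNegative = FALSE)
    expect_equal(out2[1, 2], 0)
    out3 <- gecStep(g2, empB, simB, allowNegative = TRUE)
    expect_equal(out3[1, 2], 1e-5 - 2e-4 * 0.5)

    # emp == sim is a fixed point
    expect_equal(gecStep(g, emp, emp), g)

    # unmasked entries never move
    mask <- matrix(FALSE, 2, 2)
    expect_equal(gecStep(g, emp, sim, mask = mask), g)
})

test_that("the GEC update is equivariant under region permutation", {
    set.seed(9)
    n <- 6
    perm <- sample(n)
    g <- matrix(runif(n * n), n); diag(g) <- 0
    emp <- fc_stub(random_corr(n, 1), fcForward = random_corr(n, 2))
    sim <- fc_stub(random_corr(n, 3), fcForward = random_corr(n, 4))
    mask <- g > 0.3
    diag(mask) <- FALSE
    a <- gecStep(g, emp, sim, mask = mask)[perm, perm]
    pemp <- fc_stub(emp@fc[perm, perm], emp@fcForward[perm, perm],
                    emp@fcReversal[perm, perm])
    psim <- fc_stub(sim@fc[perm, perm], sim@fcForward[perm, perm],
                    sim@fcReversal[perm, perm])
    b <- gecStep(g[perm, perm], pemp, psim, mask = mask[perm, perm])
    expect_equal(a, b)
})

test_that("negative edge fraction counts masked entries", {
    mask <- matrix(TRUE, 3, 3); diag(mask) <- FALSE
    g <- matrix(0, 3, 3)
    hist <- data.frame(iteration = 1L, fcCorrelation = 0.5)
    res <- new("GECResult", gec = g, allowNegative = TRUE, mask = mask,
               fitHistory = hist, epsilon = 2e-4, epsilonPrime = 4e-5,
               converged = TRUE, seed = 1L)
    expect_equal(negativeEdgeFraction(res), 0)
    g[1, 2] <- -1; g[2, 1] <- -1; g[1, 3] <- 1
    res2 <- initialize(res, gec = g)
    expect_equal(negativeEdgeFraction(res2), 2 / 6)

    set.seed(3)
    n <- 40
    mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
    g <- matrix(rnorm(n * n), n) * mask
    signs <- matrix(runif(n * n) < 0.3, n)
    g <- abs(g) * ifelse(signs, -1, 1) * mask
    res3 <- initialize(res, gec = g, mask = mask)
    expect_equal(negativeEdgeFraction(res3), 0.3, tolerance = 0.05)
})

test_that("fitting is self-consistent and deterministic with the linear engine", {
    fix <- tiny_cohort()
    gtw <- weights(fix$cohort$groundTruth)
    sc <- StructuralConnectome(abs(gtw))
    params <- fix$cohort$params
    emp <- gecnet:::linearized_fc_statistics(abs(gtw), params, 1L)
    fit <- fitGEC(sc, emp, params, engine = "linear", maxIter = 20L)
    expect_gte(max(fitHistory(fit)$fcCorrelation), 0.9)
    expect_equal(fitHistory(fit)$fcCorrelation[1], 1, tolerance = 1e-12)

    fit2 <- fitGEC(sc, emp, params, engine = "linear", maxIter = 20L)
    expect_identical(gecMatrix(fit), gecMatrix(fit2))
    expect_identical(fitHistory(fit), fitHistory(fit2))

    # gec stays zero off the anatomical mask
    expect_true(all(gecMatrix(fit)[!updateMask(fit)] == 0))
})

test_that("the sign constraint can only hurt the achievable fit", {
    fix <- tiny_cohort()
    gtw <- weights(fix$cohort$groundTruth)   # signed ground truth
    params <- fix$cohort$params
    sc <- StructuralConnectome(abs(gtw))
    emp <- gecnet:::linearized_fc_statistics(gtw, params, 1L)
    comp <- fitGEC(sc, emp, params, allowNegative = TRUE, engine = "linear",
                   maxIter = 400L, tolerance = 0, patience = 50L)
    coop <- fitGEC(sc, emp, params, allowNegative = FALSE, engine = "linear",
                   maxIter = 400L, tolerance = 0, patience = 50L)
    expect_true(all(gecMatrix(coop) >= 0))
    expect_gt(negativeEdgeFraction(comp), 0)
    expect_lt(max(fitHistory(coop)$fcCorrelation),
              max(fitHistory(comp)$fcCorrelation))
})

test_that("group statistics average subjects entrywise", {
    a <- fc_stub(random_corr(4, 5), fcForward = random_corr(4, 6))
    b <- fc_stub(random_corr(4, 7), fcForward = random_corr(4, 8))
    g <- groupStatistics(list(a, b))
    expect_equal(g@fc, (a@fc + b@fc) / 2)
    expect_equal(g@fcForward, (a@fcForward + b@fcForward) / 2)
    expect_error(groupStatistics(list()), "empty")
})
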