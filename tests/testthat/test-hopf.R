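test_that("a single supercritical node settles on the sqrt(a) limit cycle", {
    p <- HopfParameters(n = 1, a = 0.04, beta = 0, dt = 0.01,
                        trSeconds = 0.5, durationSeconds = 500,
                        burnInSeconds = 300, seed = 2)
    x <- signalMatrix(simulateHopf(matrix(0, 1, 1), p)$ts)[, 1]
    radius <- sqrt(2 * mean(x^2))   # RMS of a sinusoid of amplitude r
    expect_equal(radius, 0.2, tolerance = 0.01)
})

test_that("a single subcritical noise-free node decays to the origin", {
    p <- HopfParameters(n = 1, a = -0.02, beta = 0, dt = 0.05,
                        trSeconds = 0.5, durationSeconds = 500,
                        burnInSeconds = 0, seed = 2)
    x <- signalMatrix(simulateHopf(matrix(0, 1, 1), p)$ts)[, 1]
    expect_lt(abs(x[length(x)]), 1e-4)
    expect_lt(abs(x[length(x)]), abs(x[1]))
})

test_that("the noisy subcritical node peaks at its intrinsic frequency", {
    p <- HopfParameters(n = 1, a = -0.02, beta = 0.01, freqHz = 0.05,
                        trSeconds = 0.72, durationSeconds = 2000,
                        burnInSeconds = 100, seed = 4)
    ts <- simulateHopf(matrix(0, 1, 1), p)$ts
    f <- estimateIntrinsicFrequencies(ts, c(0.02, 0.09))
    expect_lt(abs(unname(f) - 0.05), 0.005)
})

test_that("intrinsic frequency estimation recovers per-region tones", {
    t <- seq(0, 1500, by = 0.72)
    set.seed(8)
    v <- cbind(sin(2 * pi * 0.04 * t), sin(2 * pi * 0.06 * t)) +
        matrix(rnorm(2 * length(t), sd = 0.1), ncol = 2)
    ts <- RegionalTimeSeries(v, 0.72)
    f <- estimateIntrinsicFrequencies(ts, c(0.02, 0.09))
    expect_lt(max(abs(unname(f) - c(0.04, 0.06))), 0.002)
    expect_lt(f[1], f[2])

    noise <- RegionalTimeSeries(matrix(rnorm(2000), 1000, 2), 0.72)
    fb <- estimateIntrinsicFrequencies(noise, c(0.04, 0.07))
    expect_true(all(fb >= 0.04 & fb <= 0.07))
})

test_that("simulation is reproducible and guards against bad input", {
    G <- matrix(c(0, 0.05, 0.05, 0), 2)
    p <- HopfParameters(n = 2, durationSeconds = 60, burnInSeconds = 10,
                        seed = 11)
    a <- simulateHopf(G, p)
    b <- simulateHopf(G, p)
    expect_identical(signalMatrix(a$ts), signalMatrix(b$ts))
    p2 <- initialize(p, seed = 12L)
    expect_false(identical(signalMatrix(a$ts),
                           signalMatrix(simulateHopf(G, p2)$ts)))
    expect_error(simulateHopf(matrix(1, 2, 3), p), "square")
    expect_error(simulateHopf(matrix(c(0, Inf, 0, 0), 2), p), "square|finite")
})

test_that("the Lyapunov solver matches the Kronecker-product oracle", {
    set.seed(21)
    G <- matrix(runif(16, 0, 0.05), 4); diag(G) <- 0; G <- (G + t(G)) / 2
    p <- HopfParameters(n = 4)
    J <- gecnet:::hopf_jacobian(G, p)
    Q <- diag(p@beta^2, 8)
    S <- gecnet:::lyapunov_solve(J, Q)
    # brute-force solve of (I (x) J + J (x) I) vec(S) = -vec(Q)
    A <- kronecker(diag(8), J) + kronecker(J, diag(8))
    oracle <- matrix(solve(A, -as.vector(Q)), 8, 8)
    expect_equal(S, oracle, tolerance = 1e-10)
    expect_lt(max(abs(S - t(S))), 1e-12)
    expect_gte(min(eigen(S, only.values = TRUE)$values), -1e-12)
})

test_that("linearized covariance reflects independence and coupling sign", {
    p <- HopfParameters(n = 3)
    lc <- linearizedCovariance(matrix(0, 3, 3), p, 1)
    expect_lt(max(abs(lc$sigma - diag(diag(lc$sigma)))), 1e-12)
    expect_equal(diag(lc$sigma), rep(diag(lc$sigma)[1], 3), tolerance = 1e-10)

    G <- matrix(c(0, 0.01, 0.01, 0), 2)
    p2 <- HopfParameters(n = 2)
    lc2 <- linearizedCovariance(G, p2, 0.72)
    expect_gt(lc2$sigma[1, 2], 0)

    # sign agrees with a long stochastic simulation
    ps <- HopfParameters(n = 2, durationSeconds = 4000, burnInSeconds = 100,
                         seed = 6)
    sim <- simulateHopf(G, ps)
    expect_gt(cov(signalMatrix(sim$ts))[1, 2], 0)

    strong <- matrix(c(0, -1, -1, 0), 2)  # destabilizing competitive pair
    expect_error(linearizedCovariance(strong, p2, 1), "unstable")
})

test_that("integration error on the FC scale is small when dt is halved", {
    # deterministic skeleton (beta = 0, supercritical): identical initial
    # conditions, so any FC difference is pure integrator error. Stochastic
    # runs cannot isolate this because the infra-slow OU decorrelation time
    # leaves too few effective samples at any desk-scale duration.
    set.seed(31)
    G <- matrix(runif(36, 0, 0.008), 6); diag(G) <- 0; G <- (G + t(G)) / 2
    fc_at <- function(dt) {
        p <- HopfParameters(n = 6, a = 0.04,
                            freqHz = seq(0.04, 0.07, length.out = 6),
                            beta = 0, dt = dt, trSeconds = 0.72,
                            durationSeconds = 1800, burnInSeconds = 200,
                            seed = 91)
        cor(signalMatrix(simulateHopf(G, p)$ts))
    }
    d <- abs(fc_at(0.72 / 7) - fc_at(0.72 / 14))
    expect_lt(max(d[upper.tri(d)]), 0.01)
})
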