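#' Reservoir configuration for the memory-capacity task
#'
#' Bundles the echo-state protocol parameters: input gain 1e-4, ridge
#' penalty 0.5, 4050 input timepoints split 70:30 train/test, 50-timepoint
#' washout, lags 1..20, spectral-radius grid 0.1..1.6 in 0.1 steps, and 10
#' repeats with random input-node draws.
#'
#' @param inputGain scalar gain on the input weights (default 1e-4).
#' @param ridgePenalty l2 penalty of the readout (default 0.5).
#' @param nTimepoints total input length; split into train/test (default
#'   4050).
#' @param trainFraction train share of \code{nTimepoints} (default 0.7).
#' @param washout initial reservoir-state timepoints discarded (default 50).
#' @param maxLag largest delay tested (default 20).
#' @param alphaGrid spectral radii tested (default \code{seq(0.1, 1.6, 0.1)}).
#' @param nRepeats input-node resampling repeats (default 10).
#' @param seed master seed.
#' @return A list of class \code{"ReservoirConfig"}.
#' @export
reservoirConfig <- function(inputGain = 1e-4, ridgePenalty = 0.5,
                            nTimepoints = 4050L, trainFraction = 0.7,
                            washout = 50L, maxLag = 20L,
                            alphaGrid = seq(0.1, 1.6, by = 0.1),
                            nRepeats = 10L, seed = 1L) {
    nTrain <- round(trainFraction * nTimepoints)
    nTest <- nTimepoints - nTrain
    if (washout + maxLag + 2 >= min(nTrain, nTest))
        stop("washout/lag leave no usable samples")
    if (any(alphaGrid <= 0)) stop("alphaGrid must be positive")
    structure(list(inputGain = inputGain, ridgePenalty = ridgePenalty,
                   nTimepoints = as.integer(nTimepoints),
                   trainFraction = trainFraction, washout = as.integer(washout),
                   maxLag = as.integer(maxLag), alphaGrid = alphaGrid,
                   nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
              class = "ReservoirConfig")
}

#' Scale a connectivity matrix to a target spectral radius
#'
#' Returns \code{alpha * w0 / rho(w0)} where \code{rho} is the largest
#' absolute eigenvalue, so the output has spectral radius \code{alpha}.
#'
#' @param w0 N x N matrix with nonzero spectral radius.
#' @param alpha target spectral radius.
#' @return Rescaled N x N matrix.
#' @export
buildReservoir <- function(w0, alpha) {
    rho <- max(Mod(eigen(w0, only.values = TRUE)$values))
    if (rho < .Machine$double.eps^0.5)
        stop("zero spectral radius (zero or nilpotent matrix)")
    alpha * w0 / rho
}

#' Run an echo-state reservoir
#'
#' Iterates \eqn{x(t+1) = \tanh(W_{in} u(t+1) + W x(t))} from a zero initial
#' state and returns the T x N state sequence.
#'
#' @param w N x N reservoir weight matrix (signed weights used as-is).
#' @param wIn N x K input matrix.
#' @param u input sequence: T-vector (K = 1) or T x K matrix.
#' @return T x N matrix of reservoir states.
#' @export
runReservoir <- function(w, wIn, u) {
    u <- as.matrix(u)
    n <- nrow(w)
    if (nrow(wIn) != n || ncol(wIn) != ncol(u))
        stop("nonconformable shapes")
    nT <- nrow(u)
    states <- matrix(0, nT, n)
    x <- numeric(n)
    for (t in seq_len(nT)) {
        x <- tanh(drop(wIn %*% u[t, ]) + drop(w %*% x))
        if (any(!is.finite(x)))
            stop(sprintf("non-finite reservoir state at step %d", t))
        states[t, ] <- x
    }
    states
}

# closed-form ridge readout with unpenalized intercept; mirrors the
# standard l2-regularized least squares min ||y - Xw - b||^2 + penalty*||w||^2
ridge_fit_predict <- function(xTrain, yTrain, xTest, penalty) {
    mx <- colMeans(xTrain)
    my <- mean(yTrain)
    xc <- sweep(xTrain, 2, mx)
    g <- crossprod(xc) + diag(penalty, ncol(xc))
    w <- solve(g, crossprod(xc, yTrain - my))
    drop(sweep(xTest, 2, mx) %*% w) + my
}

#' Memory capacity of a connectome-based reservoir
#'
#' The classical memory-capacity protocol: a uniform U(-1, 1) input stream
#' is fed into a randomly chosen half of the input pool; one ridge readout
#' per lag tau = 1..maxLag is trained on the output-node states to
#' reproduce u(t - tau); the per-lag score is the absolute Pearson
#' correlation between target and prediction on an independently generated
#' test stream, and memory capacity is the sum over lags. The weight matrix
#' is rescaled to each spectral radius in \code{alphaGrid}; per alpha, MC is
#' averaged over \code{nRepeats} input-node draws, and the best alpha's
#' average is returned (ties go to the smallest alpha).
#'
#' @param w0 N x N (signed) connectivity matrix.
#' @param inputPool candidate input node indices (half are sampled per
#'   repeat).
#' @param outputNodes readout node indices (disjoint from the input pool).
#' @param cfg a \code{\link{reservoirConfig}}.
#' @return A list with \code{mc} (averaged MC at the best alpha),
#'   \code{bestAlpha}, \code{perLagScores} (mean over repeats at the best
#'   alpha), \code{perRepeatMC} (at the best alpha) and \code{mcByAlpha}.
#' @export
memoryCapacity <- function(w0, inputPool, outputNodes,
                           cfg = reservoirConfig()) {
    n <- nrow(w0)
    inputPool <- as.integer(inputPool)
    outputNodes <- as.integer(outputNodes)
    if (!length(inputPool) || !length(outputNodes))
        stop("empty node pools")
    if (length(intersect(inputPool, outputNodes)))
        stop("input pool and output nodes must be disjoint")
    nTrain <- round(cfg$trainFraction * cfg$nTimepoints)
    nTest <- cfg$nTimepoints - nTrain
    nIn <- ceiling(length(inputPool) / 2)
    seeds <- child_seeds(cfg$seed, cfg$nRepeats * 3L)
    nAlpha <- length(cfg$alphaGrid)
    scores <- array(NA_real_, c(nAlpha, cfg$nRepeats, cfg$maxLag))
    for (rep_i in seq_len(cfg$nRepeats)) {
        inputNodes <- with_seed(seeds[3 * rep_i - 2],
                                inputPool[sample.int(length(inputPool), nIn)])
        uTrain <- with_seed(seeds[3 * rep_i - 1],
                            stats::runif(nTrain, -1, 1))
        uTest <- with_seed(seeds[3 * rep_i],
                           stats::runif(nTest, -1, 1))
        wIn <- matrix(0, n, 1)
        wIn[inputNodes, 1] <- cfg$inputGain
        for (ai in seq_len(nAlpha)) {
            # a zero/nilpotent matrix cannot be spectrally normalized; use it
            # as-is (its memory lives only in the transient structure)
            w <- tryCatch(buildReservoir(w0, cfg$alphaGrid[ai]),
                          error = function(e) w0)
            sTrain <- runReservoir(w, wIn, uTrain)[, outputNodes, drop = FALSE]
            sTest <- runReservoir(w, wIn, uTest)[, outputNodes, drop = FALSE]
            keepTr <- (cfg$washout + 1L):nTrain
            keepTe <- (cfg$washout + 1L):nTest
            for (lag in seq_len(cfg$maxLag)) {
                trIdx <- keepTr[keepTr > lag]
                teIdx <- keepTe[keepTe > lag]
                yHat <- ridge_fit_predict(sTrain[trIdx, , drop = FALSE],
                                          uTrain[trIdx - lag],
                                          sTest[teIdx, , drop = FALSE],
                                          cfg$ridgePenalty)
                yTest <- uTest[teIdx - lag]
                r <- suppressWarnings(stats::cor(yTest, yHat))
                scores[ai, rep_i, lag] <- if (is.finite(r)) abs(r) else 0
            }
        }
    }
    mcByRepeat <- apply(scores, c(1, 2), sum)
    mcByAlpha <- rowMeans(mcByRepeat)
    bestIdx <- which.max(mcByAlpha)   # which.max takes the first (smallest
                                      # alpha) on ties
    list(mc = mcByAlpha[bestIdx], bestAlpha = cfg$alphaGrid[bestIdx],
         perLagScores = apply(scores[bestIdx, , , drop = FALSE], 3, mean),
         perRepeatMC = mcByRepeat[bestIdx, ],
         mcByAlpha = stats::setNames(mcByAlpha, cfg$alphaGrid))
}
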