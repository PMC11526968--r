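#' Simulate a network of coupled stochastic Hopf oscillators
#'
#' Integrates the Stuart-Landau (supercritical Hopf normal form) network with
#' diffusive coupling by Euler-Maruyama in Cartesian coordinates:
#' \deqn{dx_n = [(a_n - x_n^2 - y_n^2) x_n - \omega_n y_n +
#'   \sum_p G_{np} (x_p - x_n)] dt + \beta \sqrt{dt}\, \eta_n}
#' and the mirrored y-equation (with \eqn{+\omega_n x_n}). A signed coupling
#' matrix enters the same diffusive term, so a negative weight inverts the
#' neighbour's influence (competitive interaction). The x component sampled
#' every TR after the burn-in is used as the BOLD proxy.
#'
#' @param coupling N x N numeric coupling matrix (possibly signed).
#' @param params a \code{\link{HopfParameters}} object.
#' @return A list with elements \code{ts} (a \code{RegionalTimeSeries} of the
#'   sampled x components), \code{params}, and \code{couplingUsed}.
#' @examples
#' p <- HopfParameters(n = 2, durationSeconds = 50, burnInSeconds = 10)
#' sim <- simulateHopf(matrix(c(0, .1, .1, 0), 2), p)
#' sim$ts
#' @export
simulateHopf <- function(coupling, params) {
    coupling <- as.matrix(coupling)
    if (nrow(coupling) != ncol(coupling) || any(!is.finite(coupling)))
        stop("coupling must be a square finite matrix")
    n <- nrow(coupling)
    if (length(params@a) != n)
        stop("params dimension does not match the coupling matrix")
    dt <- params@dt
    stepsPerTR <- round(params@trSeconds / dt)
    if (abs(stepsPerTR * dt - params@trSeconds) > 1e-9)
        stop("trSeconds must be an integer multiple of dt")
    nBurn <- ceiling(params@burnInSeconds / dt)
    nOut <- floor(params@durationSeconds / params@trSeconds)
    if (nOut < 2) stop("duration too short for the requested TR")
    nSteps <- nBurn + nOut * stepsPerTR
    a <- params@a; om <- params@omega; beta <- params@beta
    s <- rowSums(coupling)
    sqdt <- sqrt(dt)
    out <- matrix(NA_real_, nOut, n)
    with_seed(params@seed, {
        x <- stats::runif(n, -0.1, 0.1)
        y <- stats::runif(n, -0.1, 0.1)
        k <- 0L
        for (step in seq_len(nSteps)) {
            r2 <- x * x + y * y
            cx <- drop(coupling %*% x) - s * x
            cy <- drop(coupling %*% y) - s * y
            nx <- x + dt * ((a - r2) * x - om * y + cx) +
                beta * sqdt * stats::rnorm(n)
            ny <- y + dt * ((a - r2) * y + om * x + cy) +
                beta * sqdt * stats::rnorm(n)
            x <- nx; y <- ny
            if (any(!is.finite(x)) || any(!is.finite(y)))
                stop(sprintf("numeric overflow at integration step %d", step))
            if (step > nBurn && (step - nBurn) %% stepsPerTR == 0L) {
                k <- k + 1L
                out[k, ] <- x
            }
        }
    })
    ts <- RegionalTimeSeries(out[seq_len(k), , drop = FALSE],
                             trSeconds = params@trSeconds,
                             labels = colnames(coupling) %||%
                                 paste0("R", seq_len(n)))
    list(ts = ts, params = params, couplingUsed = coupling)
}

#' Estimate per-region intrinsic frequencies from narrowband signals
#'
#' Returns the peak frequency of each region's power spectral density within
#' the given band, from the band-pass filtered signal. These peak frequencies
#' set the intrinsic frequencies \eqn{\omega_n = 2\pi f_n} of the Hopf nodes;
#' averaging across subjects is done by the caller over per-subject outputs.
#'
#' @param ts a \code{RegionalTimeSeries} (filtered internally if its
#'   \code{bandHz} differs from \code{band}).
#' @param band numeric \code{c(low, high)} in Hz.
#' @return Numeric N-vector of peak frequencies (Hz).
#' @export
estimateIntrinsicFrequencies <- function(ts, band) {
    if (!length(bandHz(ts)) || any(abs(bandHz(ts) - band) > 1e-12))
        ts <- bandpassFilter(ts, band[1], band[2])
    v <- signalMatrix(ts)
    nT <- nrow(v)
    fs <- 1 / trSeconds(ts)
    freqRes <- fs / nT
    if (band[1] < freqRes)
        warning("spectral resolution coarser than the lower band edge")
    apply(v, 2, function(col) {
        sp <- stats::spec.pgram(stats::ts(col, frequency = fs), taper = 0,
                                detrend = TRUE, plot = FALSE)
        inBand <- sp$freq >= band[1] & sp$freq <= band[2]
        if (!any(inBand))
            stop("frequency band empty after discretization; T too short")
        sp$freq[inBand][which.max(sp$spec[inBand])]
    })
}

# Jacobian of the coupled Hopf system linearized at the origin, as a
# 2N x 2N block matrix [[A, -Omega], [Omega, A]] with
# A = diag(a) + G - diag(rowSums(G))
hopf_jacobian <- function(coupling, params) {
    n <- nrow(coupling)
    A <- coupling
    diag(A) <- diag(A) + params@a - rowSums(coupling)
    Om <- diag(params@omega, n)
    rbind(cbind(A, -Om), cbind(Om, A))
}

# solve J S + S J' + Q = 0 by eigendecomposition of J (J diagonalizable,
# strictly stable); returns the real symmetric solution
lyapunov_solve <- function(J, Q) {
    e <- eigen(J)
    V <- e$vectors
    W <- solve(V)
    P <- W %*% Q %*% Conj(t(W))
    denom <- outer(e$values, Conj(e$values), `+`)
    M <- -P / denom
    S <- V %*% M %*% Conj(t(V))
    S <- Re(S)
    (S + t(S)) / 2
}

#' Linearized stationary covariance of the coupled Hopf network
#'
#' Deterministic fast path for the subthreshold regime (all a_n < 0, weak
#' coupling): linearizes the network at the origin, solves the continuous
#' Lyapunov equation of the 2N-dimensional Ornstein-Uhlenbeck approximation,
#' and propagates the covariance to lag tau with the matrix exponential.
#' Returns the x-block of both.
#'
#' @param coupling N x N coupling matrix.
#' @param params a \code{HopfParameters} (only \code{a}, \code{omega},
#'   \code{beta} are used).
#' @param lagSeconds lag for the lagged covariance (s).
#' @return List with \code{sigma} (N x N zero-lag covariance of x) and
#'   \code{sigmaLag} (N x N, entry (i, j) = cov(x_i(t + lag), x_j(t))).
#' @export
linearizedCovariance <- function(coupling, params, lagSeconds) {
    coupling <- as.matrix(coupling)
    n <- nrow(coupling)
    J <- hopf_jacobian(coupling, params)
    ev <- eigen(J, only.values = TRUE)$values
    if (max(Re(ev)) >= -1e-12)
        stop("linearization unstable: coupling too strong for the linear regime")
    Q <- diag(params@beta^2, 2 * n)
    S <- lyapunov_solve(J, Q)
    e <- eigen(J)
    expJ <- Re(e$vectors %*% diag(exp(e$values * lagSeconds)) %*%
                   solve(e$vectors))
    Slag <- expJ %*% S
    xi <- seq_len(n)
    list(sigma = S[xi, xi, drop = FALSE],
         sigmaLag = Slag[xi, xi, drop = FALSE])
}

# FCStatistics implied by the linearized (stationary Gaussian) model.
# For a stationary Gaussian process the time-reversed lagged correlation is
# the transpose of the forward one.
linearized_fc_statistics <- function(coupling, params, lagTRs = 1L) {
    lc <- linearizedCovariance(coupling, params,
                               lagSeconds = lagTRs * params@trSeconds)
    sdv <- sqrt(diag(lc$sigma))
    fc <- lc$sigma / outer(sdv, sdv)
    diag(fc) <- 1
    # sigmaLag[p, n] = cov(x_p(t + lag), x_n(t)); forward entry (n, p) is
    # cor(x_n(t), x_p(t + lag))
    fcF <- t(lc$sigmaLag) / outer(sdv, sdv)
    new("FCStatistics", fc = fc, fcForward = fcF, fcReversal = t(fcF),
        lagTRs = as.integer(lagTRs))
}
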