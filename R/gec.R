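#' Zero-lag and time-shifted FC statistics
#'
#' Computes the zero-lag Pearson correlation matrix, the forward time-shifted
#' correlation matrix at a fixed lag (entry (n, p) is
#' \code{cor(x_n(t), x_p(t + lag))} over the overlapping samples), and the
#' same shifted statistic computed after reversing the time axis of every
#' column. The forward/reversal pair carries the temporal-asymmetry
#' information the GEC update and the irreversibility analysis use.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param lagTRs lag in sampling periods (default 1).
#' @return An \code{\link{FCStatistics}} object.
#' @examples
#' ts <- RegionalTimeSeries(matrix(rnorm(400), 100, 4), trSeconds = 1)
#' fcStatistics(ts)
#' @export
fcStatistics <- function(ts, lagTRs = 1L) {
    v <- signalMatrix(ts)
    nT <- nrow(v)
    lagTRs <- as.integer(lagTRs)
    if (nT <= lagTRs + 2L) stop("time series too short for the requested lag")
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
        stop("constant regions (correlation undefined): ",
             paste(regionLabels(ts)[sds == 0], collapse = ", "))
    fc <- stats::cor(v)
    fc <- (fc + t(fc)) / 2
    diag(fc) <- 1
    shifted_cor <- function(m) {
        stats::cor(m[seq_len(nT - lagTRs), , drop = FALSE],
                   m[(1L + lagTRs):nT, , drop = FALSE])
    }
    vr <- v[nT:1, , drop = FALSE]
    new("FCStatistics", fc = fc, fcForward = shifted_cor(v),
        fcReversal = shifted_cor(vr), lagTRs = lagTRs)
}

#' Average FC statistics across subjects
#'
#' Entrywise mean of the zero-lag, forward and reversal matrices over a list
#' of \code{\link{FCStatistics}} (all at the same lag), for group-level GEC
#' fitting.
#'
#' @param statsList non-empty list of \code{FCStatistics}.
#' @return An \code{FCStatistics} of the group averages.
#' @export
groupStatistics <- function(statsList) {
    if (!length(statsList)) stop("empty list")
    lags <- vapply(statsList, function(s) s@lagTRs, integer(1))
    if (length(unique(lags)) != 1L) stop("mixed lags")
    avg <- function(get) Reduce(`+`, lapply(statsList, get)) / length(statsList)
    new("FCStatistics", fc = avg(function(s) s@fc),
        fcForward = avg(function(s) s@fcForward),
        fcReversal = avg(function(s) s@fcReversal), lagTRs = lags[1])
}

#' One heuristic gradient update of the generative effective connectivity
#'
#' Applies, on the masked entries only,
#' \deqn{GEC \leftarrow GEC + \epsilon (FC^{emp} - FC^{sim}) -
#'   \epsilon' ([FC_f^{emp} - FC_r^{emp}] - [FC_f^{sim} - FC_r^{sim}])}
#' where \eqn{FC_f}/\eqn{FC_r} are the forward/reversal time-shifted
#' correlations. In the cooperative-only variant
#' (\code{allowNegative = FALSE}) entries that would become negative are
#' clamped at zero; clamped edges may later re-grow positive.
#'
#' @param gec current N x N coupling matrix.
#' @param emp,sim \code{FCStatistics} of the empirical and simulated series.
#' @param epsilon learning rate on the zero-lag FC error (default 2e-4).
#' @param epsilonPrime learning rate on the lagged asymmetry error
#'   (default 4e-5).
#' @param mask N x N logical matrix of updatable entries (default: all
#'   off-diagonal).
#' @param allowNegative permit competitive (negative) couplings?
#' @return The updated N x N matrix.
#' @export
gecStep <- function(gec, emp, sim, epsilon = 2e-4, epsilonPrime = 4e-5,
                    mask = NULL, allowNegative = TRUE) {
    if (is.null(mask)) {
        mask <- matrix(TRUE, nrow(gec), ncol(gec))
        diag(mask) <- FALSE
    }
    upd <- epsilon * (emp@fc - sim@fc) -
        epsilonPrime * ((emp@fcForward - emp@fcReversal) -
                        (sim@fcForward - sim@fcReversal))
    if (any(!is.finite(upd))) stop("non-finite update")
    out <- gec
    out[mask] <- gec[mask] + upd[mask]
    if (!allowNegative) out[mask & out < 0] <- 0
    out
}

#' Fit generative effective connectivity to empirical FC statistics
#'
#' Iterates \{simulate the coupled Hopf model on the current GEC, measure its
#' FC statistics, apply \code{\link{gecStep}}\} starting from the anatomical
#' connectome, until the empirical-vs-simulated FC correlation stabilizes.
#' Updates are applied only to the known anatomical support (nonzero entries
#' of \code{sc}); the forward/reversal term can break symmetry, so a
#' symmetric anatomical prior does not force a symmetric GEC.
#'
#' Two engines are available: \code{"stochastic"} (Euler-Maruyama simulation,
#' a fresh seeded noise stream per iteration) and \code{"linear"} (the
#' linearized-covariance fast path, deterministic). The best-fitting iterate
#' encountered is returned, so simulation noise cannot degrade the reported
#' model.
#'
#' @param sc prepared \code{StructuralConnectome} (initialization and mask).
#' @param emp \code{FCStatistics} of the (band-matched) empirical series.
#' @param params \code{HopfParameters} used for the per-iteration
#'   simulations; \code{durationSeconds} defaults to 500 TR if not set by
#'   \code{iterationDuration}.
#' @param allowNegative permit competitive couplings (default TRUE).
#' @param engine \code{"stochastic"} or \code{"linear"}.
#' @param lagTRs lag of the shifted-correlation term (default 1 TR, matching
#'   the irreversibility analysis).
#' @param epsilon,epsilonPrime learning rates (defaults 2e-4 and 4e-5).
#' @param maxIter maximum number of iterations (default 200).
#' @param tolerance convergence tolerance on the fit correlation
#'   (default 1e-3 over \code{tolWindow} iterations).
#' @param tolWindow convergence window (default 10 iterations).
#' @param patience consecutive fit decreases counted as divergence
#'   (default 20).
#' @param iterationDuration simulated seconds per stochastic iteration
#'   (default 500 TR).
#' @param seed master seed for the per-iteration noise streams.
#' @return A \code{\link{GECResult}}.
#' @export
fitGEC <- function(sc, emp, params, allowNegative = TRUE,
                   engine = c("stochastic", "linear"), lagTRs = 1L,
                   epsilon = 2e-4, epsilonPrime = 4e-5, maxIter = 200L,
                   tolerance = 1e-3, tolWindow = 10L, patience = 20L,
                   iterationDuration = NULL, seed = 1L) {
    engine <- match.arg(engine)
    w0 <- weights(sc)
    if (nrow(w0) != nrow(emp@fc))
        stop("connectome and FC statistics dimensions disagree")
    mask <- w0 != 0
    diag(mask) <- FALSE
    if (!any(mask)) stop("empty anatomical mask")
    gec <- w0
    if (!allowNegative) gec[gec < 0] <- 0
    itDur <- iterationDuration %||% (500 * params@trSeconds)
    seeds <- child_seeds(seed, maxIter)
    hist <- data.frame(iteration = integer(0), fcCorrelation = numeric(0))
    best <- list(r = -Inf, gec = gec)
    decreasing <- 0L
    converged <- FALSE
    lastR <- -Inf
    for (iter in seq_len(maxIter)) {
        sim <- tryCatch({
            if (engine == "stochastic") {
                p <- initialize(params, durationSeconds = itDur,
                                seed = seeds[iter])
                fcStatistics(simulateHopf(gec, p)$ts, lagTRs = lagTRs)
            } else {
                linearized_fc_statistics(gec, params, lagTRs = lagTRs)
            }
        }, error = function(e) e)
        if (inherits(sim, "error")) {
            warning("fit stopped at iteration ", iter, ": ",
                    conditionMessage(sim))
            break
        }
        r <- uptri_cor(emp@fc, sim@fc)
        hist <- rbind(hist, data.frame(iteration = iter, fcCorrelation = r))
        if (r > best$r) best <- list(r = r, gec = gec)
        decreasing <- if (r < lastR) decreasing + 1L else 0L
        lastR <- r
        if (decreasing >= patience) break
        if (iter >= tolWindow + 1L) {
            recent <- hist$fcCorrelation[(iter - tolWindow):iter]
            if (max(recent) - recent[1] < tolerance &&
                max(hist$fcCorrelation) - recent[1] < tolerance) {
                converged <- TRUE
                break
            }
        }
        gec <- gecStep(gec, emp, sim, epsilon = epsilon,
                       epsilonPrime = epsilonPrime, mask = mask,
                       allowNegative = allowNegative)
    }
    hist$best <- cummax(hist$fcCorrelation)
    new("GECResult", gec = best$gec, allowNegative = allowNegative,
        mask = mask, fitHistory = hist, epsilon = epsilon,
        epsilonPrime = epsilonPrime, converged = converged,
        seed = as.integer(seed))
}

#' Fraction of negative edges in a fitted GEC
#'
#' @param gec a \code{GECResult}.
#' @return Fraction of masked entries that are strictly negative.
#' @export
negativeEdgeFraction <- function(gec) {
    m <- updateMask(gec)
    if (!any(m)) stop("empty mask")
    sum(gecMatrix(gec)[m] < 0) / sum(m)
}
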