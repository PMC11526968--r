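#' Gaussian mutual information between two variable subsets
#'
#' For a joint Gaussian with covariance \code{cov}, returns
#' \deqn{I(A;B) = \frac{1}{2} \log \frac{\det\Sigma_A \det\Sigma_B}
#'   {\det\Sigma_{AB}}}
#' in nats. A numerically singular joint covariance is regularized by adding
#' 1e-10 to the diagonal (with a message).
#'
#' @param cov covariance matrix (positive semi-definite).
#' @param idxA,idxB disjoint, non-empty index sets into \code{cov}.
#' @return Mutual information in nats.
#' @examples
#' gaussianMI(matrix(c(1, .5, .5, 1), 2), 1, 2)  # -0.5*log(1-0.25)
#' @export
gaussianMI <- function(cov, idxA, idxB) {
    if (!length(idxA) || !length(idxB) || length(intersect(idxA, idxB)))
        stop("index sets must be disjoint and non-empty")
    ab <- c(idxA, idxB)
    dA <- det(cov[idxA, idxA, drop = FALSE])
    dB <- det(cov[idxB, idxB, drop = FALSE])
    dAB <- det(cov[ab, ab, drop = FALSE])
    if (dAB <= 0 || dA <= 0 || dB <= 0) {
        message("gaussianMI: singular covariance regularized (1e-10 jitter)")
        cov <- cov + diag(1e-10, nrow(cov))
        dA <- det(cov[idxA, idxA, drop = FALSE])
        dB <- det(cov[idxB, idxB, drop = FALSE])
        dAB <- det(cov[ab, ab, drop = FALSE])
    }
    max(0, 0.5 * log(dA * dB / dAB))
}

#' Lagged covariance of a region pair
#'
#' Sample covariance (unbiased) of the stacked 4-vector
#' (X_\{t-tau\}, Y_\{t-tau\}, X_t, Y_t) over the T - tau aligned samples,
#' after standardizing each region's full series. This is the sufficient
#' statistic for the Gaussian integrated information decomposition.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param n,p region indices (1-based).
#' @param tauTRs lag in sampling periods (default 1).
#' @return A list with \code{cov} (4 x 4, variables ordered past-X, past-Y,
#'   future-X, future-Y), \code{tauTRs} and \code{pair}.
#' @export
laggedPairCovariance <- function(ts, n, p, tauTRs = 1L) {
    v <- signalMatrix(ts)
    nT <- nrow(v)
    tauTRs <- as.integer(tauTRs)
    if (nT <= tauTRs + 3L) stop("time series too short for the requested lag")
    x <- v[, n]; y <- v[, p]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant region; covariance undefined")
    x <- as.numeric(scale(x)); y <- as.numeric(scale(y))
    past <- seq_len(nT - tauTRs)
    fut <- past + tauTRs
    m <- cbind(xp = x[past], yp = y[past], xf = x[fut], yf = y[fut])
    list(cov = stats::cov(m), tauTRs = tauTRs, pair = c(n, p))
}

# antichains of two sources and their member subsets; past variables are
# cov indices 1:2, future variables 3:4
.phiid_antichains <- list(
    rr = list(1L, 2L),       # {1}{2}
    x  = list(1L),           # {1}
    y  = list(2L),           # {2}
    s  = list(c(1L, 2L)))    # {12}

# down-sets under {1}{2} < {1},{2} < {12}
.phiid_downsets <- list(rr = "rr", x = c("rr", "x"), y = c("rr", "y"),
                        s = c("rr", "x", "y", "s"))

#' Gaussian MMI integrated information decomposition of a region pair
#'
#' Decomposes the time-delayed mutual information
#' \eqn{I(X_{t-\tau}, Y_{t-\tau}; X_t, Y_t)} into the 16 atoms of
#' integrated information decomposition under the minimum-mutual-information
#' (MMI) redundancy function. The cumulative double-redundancy of an
#' antichain pair \eqn{\alpha \to \beta} is the minimum Gaussian mutual
#' information between any past subset in \eqn{\alpha} and any future subset
#' in \eqn{\beta}; atoms are recovered by Moebius inversion over the product
#' of the two antichain lattices. In particular the persistent redundancy
#' atom's cumulative value is
#' \eqn{\min\{I(X_p;X_f), I(X_p;Y_f), I(Y_p;X_f), I(Y_p;Y_f)\}} and the
#' persistent synergy atom ("s->s") is the headline statistic.
#'
#' @param lpc output of \code{\link{laggedPairCovariance}} (or any list with
#'   a 4 x 4 \code{cov} in past-X, past-Y, future-X, future-Y order).
#' @return A \code{\link{PhiIDAtoms}} object (atoms in nats).
#' @export
phiidMMI <- function(lpc) {
    cv <- lpc$cov
    futureOf <- function(subset) subset + 2L
    redFun <- function(alpha, beta) {
        vals <- c()
        for (a in .phiid_antichains[[alpha]])
            for (b in .phiid_antichains[[beta]])
                vals <- c(vals, gaussianMI(cv, a, futureOf(b)))
        min(vals)
    }
    nms <- names(.phiid_antichains)
    atomsM <- matrix(NA_real_, 4, 4, dimnames = list(nms, nms))
    for (alpha in nms) {
        for (beta in nms) {
            below <- expand.grid(a = .phiid_downsets[[alpha]],
                                 b = .phiid_downsets[[beta]],
                                 stringsAsFactors = FALSE)
            below <- below[!(below$a == alpha & below$b == beta), ]
            acc <- if (nrow(below))
                sum(atomsM[cbind(below$a, below$b)]) else 0
            atomsM[alpha, beta] <- redFun(alpha, beta) - acc
        }
    }
    atomNames <- as.vector(outer(nms, nms, function(a, b) paste0(a, "->", b)))
    atomsV <- as.vector(atomsM)  # column-major: varies over alpha first
    names(atomsV) <- atomNames
    tdmiVal <- gaussianMI(cv, 1:2, 3:4)
    new("PhiIDAtoms", atoms = atomsV, tdmi = tdmiVal,
        tauTRs = as.integer(lpc$tauTRs %||% 1L),
        pair = as.integer(lpc$pair %||% c(0L, 0L)))
}

#' Persistent-synergy profile across all region pairs
#'
#' Runs the Gaussian MMI integrated information decomposition on every
#' unordered region pair and collects the temporally persistent synergy atom
#' into a symmetric matrix; the scalar summary is the mean over pairs.
#' Pairs whose decomposition fails are excluded from the mean and counted.
#'
#' @param ts a \code{RegionalTimeSeries} with at least 2 regions.
#' @param tauTRs lag in sampling periods (default 1).
#' @return A list with \code{synergy} (N x N symmetric, NA diagonal),
#'   \code{meanSynergy} and \code{nFailed}.
#' @export
synergyProfile <- function(ts, tauTRs = 1L) {
    n <- ncol(signalMatrix(ts))
    if (n < 2) stop("need at least 2 regions")
    syn <- matrix(NA_real_, n, n,
                  dimnames = list(regionLabels(ts), regionLabels(ts)))
    nFailed <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            res <- tryCatch(
                synergyPersistent(phiidMMI(
                    laggedPairCovariance(ts, i, j, tauTRs = tauTRs))),
                error = function(e) NA_real_)
            if (is.na(res)) nFailed <- nFailed + 1L
            syn[i, j] <- syn[j, i] <- res
        }
    }
    vals <- syn[upper.tri(syn)]
    list(synergy = syn, meanSynergy = mean(vals, na.rm = TRUE),
         nFailed = nFailed)
}
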