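#' Correlation-based model fit between two FC matrices
#'
#' Pearson correlation over the strictly-upper-triangle entries of the
#' empirical and simulated FC matrices — the standard scalar fit measure for
#' generative whole-brain models.
#'
#' @param fcEmp,fcSim N x N symmetric matrices.
#' @return Correlation coefficient.
#' @export
fcFit <- function(fcEmp, fcSim) {
    if (!all(dim(fcEmp) == dim(fcSim))) stop("shape mismatch")
    uptri_cor(fcEmp, fcSim)
}

#' Structural similarity index between two FC matrices
#'
#' Single-scale SSIM treating each matrix as an image, in its global
#' (whole-image statistics, no sliding window) variant:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with stabilizers \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2} and L the
#' joint value range of the two matrices. Unlike the correlation fit, SSIM
#' is sensitive to differences in mean and variance, not only pattern.
#'
#' @param fcEmp,fcSim same-shape numeric matrices.
#' @return SSIM value in [-1, 1].
#' @export
fcSSIM <- function(fcEmp, fcSim) {
    if (!all(dim(fcEmp) == dim(fcSim))) stop("shape mismatch")
    x <- as.numeric(fcEmp); y <- as.numeric(fcSim)
    L <- max(c(x, y)) - min(c(x, y))
    if (L == 0) stop("zero joint value range")
    c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + c1) * (2 * sxy + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Differential identifiability of a simulated cohort
#'
#' Builds the S x S identifiability matrix A whose entry (i, j) is the
#' upper-triangle correlation between simulated subject i's FC and empirical
#' subject j's FC. Self-identifiability \eqn{I_{self}} is the mean diagonal,
#' \eqn{I_{others}} the mean off-diagonal, and the differential
#' identifiability \eqn{I_{diff} = I_{self} - I_{others}} quantifies the
#' model's subject-specificity.
#'
#' @param empFCs,simFCs equal-length lists of N x N FC matrices (same
#'   subject order).
#' @return A list with \code{similarity} (S x S), \code{iSelf},
#'   \code{iOthers} and \code{iDiff}.
#' @export
identifiability <- function(empFCs, simFCs) {
    s <- length(empFCs)
    if (length(simFCs) != s) stop("lists must have equal length")
    if (s < 2) stop("need at least 2 subjects")
    A <- matrix(NA_real_, s, s)
    for (i in seq_len(s))
        for (j in seq_len(s))
            A[i, j] <- fcFit(simFCs[[i]], empFCs[[j]])
    iSelf <- mean(diag(A))
    iOthers <- mean(A[row(A) != col(A)])
    list(similarity = A, iSelf = iSelf, iOthers = iOthers,
         iDiff = iSelf - iOthers)
}

#' Cognitive matching of activity against a map bank
#'
#' For every volume, the activity pattern across regions is spatially
#' correlated against each map in the bank; the volume's matching score is
#' the largest positive correlation across maps (floored at 0 when no map
#' correlates positively). The scan score is the mean over volumes.
#'
#' @param ts a \code{RegionalTimeSeries} (N regions).
#' @param maps N x K numeric matrix of map vectors over the same regions
#'   (columns may be named).
#' @return A list with \code{perVolume} (T-vector of best scores),
#'   \code{bestMap} (index of the best map per volume, NA when floored),
#'   \code{scanScore} and \code{nFloored} (volumes with no positive match,
#'   including constant volumes).
#' @export
cognitiveMatching <- function(ts, maps) {
    v <- signalMatrix(ts)
    maps <- as.matrix(maps)
    if (nrow(maps) != ncol(v))
        stop("map bank regions must align with time-series columns")
    if (any(apply(maps, 2, stats::sd) == 0))
        stop("constant map column in the bank")
    nT <- nrow(v)
    perVolume <- numeric(nT)
    bestMap <- rep(NA_integer_, nT)
    nFloored <- 0L
    for (t in seq_len(nT)) {
        act <- v[t, ]
        if (stats::sd(act) == 0) {
            nFloored <- nFloored + 1L
            next
        }
        r <- suppressWarnings(stats::cor(act, maps))
        best <- which.max(r)
        if (is.finite(r[best]) && r[best] > 0) {
            perVolume[t] <- r[best]
            bestMap[t] <- best
        } else nFloored <- nFloored + 1L
    }
    list(perVolume = perVolume, bestMap = bestMap,
         scanScore = mean(perVolume), nFloored = nFloored)
}

#' Resampling-based paired comparison with Hedges' g
#'
#' Paired-samples t statistic on the differences a - b, with a two-sided
#' p-value from sign-flip resampling of the differences (the exceedance
#' probability of |t| under random sign flips, with add-one correction).
#' The effect size is Hedges' g: the mean difference over the pooled SD of
#' the two samples, times the small-sample correction
#' \eqn{1 - 3 / (4(2S - 2) - 1)}.
#'
#' @param a,b equal-length numeric vectors (paired samples, S >= 3).
#' @param nResamples number of sign-flip draws (default 10000).
#' @param seed RNG seed for the resampling.
#' @return A list with \code{meanA}, \code{sdA}, \code{meanB}, \code{sdB},
#'   \code{tStatistic}, \code{pResampled}, \code{hedgesG}, \code{nPairs},
#'   \code{nResamples}, \code{seed}.
#' @export
pairedComparison <- function(a, b, nResamples = 10000L, seed = 1L) {
    s <- length(a)
    if (length(b) != s) stop("paired vectors must have equal length")
    if (s < 3) stop("need at least 3 pairs")
    d <- a - b
    out <- list(meanA = mean(a), sdA = stats::sd(a), meanB = mean(b),
                sdB = stats::sd(b), nPairs = s,
                nResamples = as.integer(nResamples), seed = as.integer(seed))
    sPooled <- sqrt(((s - 1) * stats::var(a) + (s - 1) * stats::var(b)) /
                        (2 * s - 2))
    corr <- 1 - 3 / (4 * (2 * s - 2) - 1)
    out$hedgesG <- if (sPooled == 0) 0 else (mean(a) - mean(b)) / sPooled * corr
    if (stats::sd(d) == 0) {
        if (all(d == 0)) {
            out$tStatistic <- 0
            out$pResampled <- 1
            return(out)
        }
        # constant nonzero shift: |t| is infinite only for the all-same-sign
        # flips, so work on the sign pattern directly
        tObs <- Inf
    } else {
        tObs <- mean(d) / (stats::sd(d) / sqrt(s))
    }
    out$tStatistic <- tObs
    tNull <- with_seed(seed, {
        flips <- matrix(stats::runif(s * nResamples) < 0.5, s, nResamples)
        vapply(seq_len(nResamples), function(k) {
            dk <- ifelse(flips[, k], -d, d)
            if (stats::sd(dk) == 0) Inf * sign(mean(dk))
            else mean(dk) / (stats::sd(dk) / sqrt(s))
        }, numeric(1))
    })
    out$pResampled <- (1 + sum(abs(tNull) >= abs(tObs) - 1e-12)) /
        (nResamples + 1)
    out
}
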