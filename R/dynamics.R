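#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes the analytic signal \eqn{z(t) = s(t) + iH[s(t)]} of every
#' (band-passed) column and returns instantaneous phases (radians, wrapped to
#' (-pi, pi]) and amplitudes. The first and last 5\% of samples are flagged
#' as edge-affected for downstream trimming.
#'
#' @param ts a band-passed \code{RegionalTimeSeries} (\code{bandHz} must be
#'   set); columns should be zero-mean after filtering.
#' @return A list with \code{phases} (T x N), \code{amplitudes} (T x N) and
#'   \code{edgeMask} (logical T-vector, TRUE where edge-affected).
#' @export
extractPhases <- function(ts) {
    if (!length(bandHz(ts)))
        stop("extractPhases requires band-passed input (bandHz unset); ",
             "apply bandpassFilter first")
    v <- signalMatrix(ts)
    z <- apply(v, 2, analytic_signal)
    nT <- nrow(v)
    nEdge <- ceiling(0.05 * nT)
    edge <- rep(FALSE, nT)
    edge[c(seq_len(nEdge), (nT - nEdge + 1L):nT)] <- TRUE
    list(phases = Arg(z), amplitudes = Mod(z), edgeMask = edge)
}

#' Kuramoto order parameter and metastability
#'
#' The instantaneous Kuramoto order parameter,
#' \deqn{KOP_t = |\sum_k e^{i\phi_k(t)}| / N,}
#' measures global phase synchrony in [0, 1]. Its standard deviation over
#' time (population SD) is the metastability signature; the maximum over
#' time is the peak global synchrony.
#'
#' @param phases output of \code{\link{extractPhases}} (or any list with a
#'   T x N \code{phases} matrix and optional \code{edgeMask}).
#' @param trimEdges drop edge-affected samples before the summary statistics
#'   (default TRUE when an \code{edgeMask} is present).
#' @return A list with \code{kop} (T-vector on the retained samples),
#'   \code{metastability} and \code{maxSync}.
#' @export
kuramotoOrder <- function(phases, trimEdges = TRUE) {
    ph <- phases$phases
    if (ncol(ph) < 2) stop("need at least 2 regions")
    kop <- Mod(rowMeans(exp(1i * ph)))
    keep <- rep(TRUE, length(kop))
    if (trimEdges && !is.null(phases$edgeMask)) keep <- !phases$edgeMask
    kop <- kop[keep]
    list(kop = kop, metastability = sd_pop(kop), maxSync = max(kop))
}

#' Intrinsic-driven ignition and its local-global hierarchy
#'
#' Each region's signal is z-scored; an event is an upward crossing of
#' z = \code{zThreshold} (z above threshold while the previous sample was
#' not). For every driver event of region i at time t, the active set is the
#' set of regions with an event inside the window [t, t + window - 1]; the
#' all-pairs co-occurrence matrix over this set is a clique, so the breadth
#' of the ignition equals the active-set size. A region's mean
#' intrinsic-driven ignition (IDI) is the mean breadth over its driver
#' events; regions with no events are excluded. The hierarchy is the
#' population SD of mean IDI across (included) regions.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param zThreshold event threshold in SD units (default 1).
#' @param windowTRs co-activation window length in TRs (default 4).
#' @return A list with \code{eventRaster} (T x N logical),
#'   \code{events} (data.frame region/time/breadth per driver event),
#'   \code{meanIDI} (N-vector, NA for event-free regions) and
#'   \code{hierarchy}.
#' @export
ignition <- function(ts, zThreshold = 1, windowTRs = 4L) {
    v <- signalMatrix(ts)
    nT <- nrow(v); n <- ncol(v)
    if (windowTRs >= nT) stop("window must be shorter than the series")
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0)) stop("constant region(s); z-scoring undefined")
    z <- scale(v)
    above <- z > zThreshold
    raster <- above & !rbind(FALSE, above[-nT, , drop = FALSE])
    if (!any(raster)) stop("no threshold crossings; ignition undefined")
    ev <- which(raster, arr.ind = TRUE)
    events <- data.frame(region = ev[, "col"], time = ev[, "row"])
    events <- events[order(events$time, events$region), ]
    breadth <- vapply(seq_len(nrow(events)), function(k) {
        t0 <- events$time[k]
        win <- raster[t0:min(nT, t0 + windowTRs - 1L), , drop = FALSE]
        sum(colSums(win) > 0)
    }, numeric(1))
    events$breadth <- breadth
    meanIDI <- vapply(seq_len(n), function(i) {
        b <- events$breadth[events$region == i]
        if (!length(b)) NA_real_ else mean(b)
    }, numeric(1))
    list(eventRaster = raster, events = events, meanIDI = meanIDI,
         hierarchy = sd_pop(meanIDI[!is.na(meanIDI)]))
}

#' Temporal irreversibility and its hierarchy
#'
#' Quantifies the arrow of time of the multivariate series from the
#' difference between forward and time-reversed lagged correlations. With
#' \eqn{c_f(n,p) = cor(x_n(t), x_p(t+T))} and \eqn{c_r} the same statistic
#' on the reversed series, the pairwise irreversibility is
#' \eqn{I_{np} = |c_f - c_r|}; the mutual-information reading maps each
#' correlation to \eqn{FS = -\frac{1}{2}\log(1 - c^2)} (the Gaussian mutual
#' information), and \eqn{FS_{diff} = (FS_f - FS_r)^2}. The hierarchy is the
#' population SD of the off-diagonal \eqn{FS_{diff}} entries; per-region
#' mean \eqn{FS_{diff}} gives the send-receive view, whose across-region SD
#' is also returned.
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param lagTRs lag T in sampling periods (default 1).
#' @return A list with \code{cForward}, \code{cReversed},
#'   \code{pairIrreversibility}, \code{fsForward}, \code{fsReversed},
#'   \code{fsDiff}, \code{regionMeanFsDiff}, \code{hierarchy} (SD over
#'   off-diagonal fsDiff elements) and \code{hierarchyRegional} (SD over
#'   regional means).
#' @export
irreversibility <- function(ts, lagTRs = 1L) {
    st <- fcStatistics(ts, lagTRs = lagTRs)
    cf <- st@fcForward
    cr <- st@fcReversal
    capc <- function(m) {
        hit <- abs(m) >= 1
        if (any(hit)) {
            message("irreversibility: |c| = 1 capped at 1 - 1e-12")
            m[hit] <- sign(m[hit]) * (1 - 1e-12)
        }
        m
    }
    fsf <- -0.5 * log(1 - capc(cf)^2)
    fsr <- -0.5 * log(1 - capc(cr)^2)
    fsd <- (fsf - fsr)^2
    off <- !diag(nrow(fsd))
    regional <- rowMeans(fsd * off) * nrow(fsd) / (nrow(fsd) - 1)
    list(cForward = cf, cReversed = cr,
         pairIrreversibility = abs(cf - cr),
         fsForward = fsf, fsReversed = fsr, fsDiff = fsd,
         regionMeanFsDiff = regional,
         hierarchy = sd_pop(fsd[off]),
         hierarchyRegional = sd_pop(regional))
}
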