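#' @import methods
NULL

.check_square_finite <- function(w) {
    if (!is.matrix(w) || nrow(w) != ncol(w))
        return("'weights' must be a square matrix")
    if (!is.numeric(w) || any(!is.finite(w)))
        return("'weights' must be numeric and finite")
    NULL
}

#' StructuralConnectome: a region-by-region coupling matrix
#'
#' Container for an N x N structural (or effective) coupling matrix with
#' region labels and optional 3-D region centroid coordinates (mm). The
#' diagonal is always zero; an undirected connectome has a symmetric weight
#' matrix.
#'
#' @slot weights N x N numeric coupling matrix (arbitrary units).
#' @slot labels character vector of N region names.
#' @slot coords N x 3 numeric matrix of centroid coordinates in mm, or a
#'   0-row matrix when coordinates are unavailable.
#' @slot directed logical; \code{FALSE} means \code{weights} is symmetric.
#' @slot speciesTag free-text provenance tag (e.g. "human", "synthetic").
#'
#' @examples
#' sc <- StructuralConnectome(matrix(c(0, 1, 1, 0), 2))
#' weights(sc)
#' @export
setClass("StructuralConnectome",
    representation(weights = "matrix", labels = "character",
                   coords = "matrix", directed = "logical",
                   speciesTag = "character"),
    prototype(coords = matrix(numeric(0), 0, 3), directed = FALSE,
              speciesTag = "unspecified"))

setValidity("StructuralConnectome", function(object) {
    w <- object@weights
    msg <- .check_square_finite(w)
    if (!is.null(msg)) return(msg)
    n <- nrow(w)
    if (any(abs(diag(w)) > 0))
        return("diagonal of 'weights' must be zero")
    if (length(object@labels) != n)
        return(sprintf("expected %d labels, got %d", n, length(object@labels)))
    if (nrow(object@coords) != 0L) {
        if (nrow(object@coords) != n || ncol(object@coords) != 3L)
            return("'coords' must be N x 3 (or empty)")
        if (any(!is.finite(object@coords)))
            return("'coords' must be finite")
    }
    if (!object@directed && max(abs(w - t(w))) > 1e-12)
        return("undirected connectome must have symmetric weights (tol 1e-12)")
    TRUE
})

#' @param weights N x N numeric matrix.
#' @param labels optional character vector of region names; defaults to
#'   \code{"R1" ... "RN"}.
#' @param coords optional N x 3 numeric matrix (mm).
#' @param directed logical; if missing, inferred from matrix symmetry.
#' @param speciesTag free-text tag.
#' @return A \code{StructuralConnectome} object.
#' @rdname StructuralConnectome-class
#' @export
StructuralConnectome <- function(weights, labels = NULL, coords = NULL,
                                 directed = NULL, speciesTag = "unspecified") {
    weights <- as.matrix(weights)
    storage.mode(weights) <- "double"
    if (nrow(weights) != ncol(weights))
        stop("'weights' must be a square matrix")
    n <- nrow(weights)
    if (is.null(labels)) labels <- paste0("R", seq_len(n))
    if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
    coords <- as.matrix(coords)
    if (nrow(coords)) storage.mode(coords) <- "double"
    if (is.null(directed))
        directed <- nrow(weights) > 0 && max(abs(weights - t(weights))) > 1e-12
    dimnames(weights) <- list(labels, labels)
    new("StructuralConnectome", weights = weights, labels = as.character(labels),
        coords = coords, directed = directed, speciesTag = speciesTag)
}

setMethod("show", "StructuralConnectome", function(object) {
    n <- nrow(object@weights)
    nz <- sum(object@weights[upper.tri(object@weights)] != 0)
    cat("StructuralConnectome:", n, "regions,",
        if (object@directed) "directed," else "undirected,",
        nz, "nonzero upper-triangle edges\n")
    cat("  species:", object@speciesTag,
        "| coords:", if (nrow(object@coords)) "yes" else "no", "\n")
    neg <- sum(object@weights < 0)
    if (neg > 0) cat("  signed:", neg, "negative entries\n")
})

#' RegionalTimeSeries: parcellated regional signals
#'
#' A T x N matrix of regional signals sampled every \code{trSeconds} seconds,
#' with an optional record of the band (Hz) the signals were filtered to.
#'
#' @slot values T x N numeric matrix (time along rows).
#' @slot trSeconds sampling period in seconds.
#' @slot bandHz numeric of length 2 \code{c(low, high)} in Hz, or length 0
#'   when the signal is broadband/unfiltered.
#' @slot labels character vector of N region names.
#' @examples
#' ts <- RegionalTimeSeries(matrix(rnorm(40), 20, 2), trSeconds = 0.72)
#' trSeconds(ts)
#' @export
setClass("RegionalTimeSeries",
    representation(values = "matrix", trSeconds = "numeric",
                   bandHz = "numeric", labels = "character"),
    prototype(bandHz = numeric(0)))

setValidity("RegionalTimeSeries", function(object) {
    v <- object@values
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
        return("'values' must be finite numeric with no missing entries")
    if (nrow(v) < 2L) return("need at least 2 time points")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
        return("'trSeconds' must be a single positive number")
    if (!length(object@bandHz) %in% c(0L, 2L))
        return("'bandHz' must have length 0 or 2")
    if (length(object@bandHz) == 2L &&
        !(object@bandHz[1] > 0 && object@bandHz[2] > object@bandHz[1]))
        return("'bandHz' must satisfy 0 < low < high")
    if (length(object@labels) != ncol(v))
        return("label count must match the number of regions")
    TRUE
})

#' @param values T x N numeric matrix.
#' @param trSeconds sampling period (s).
#' @param bandHz optional \code{c(low, high)} in Hz.
#' @param labels optional region names (default taken from column names).
#' @return A \code{RegionalTimeSeries} object.
#' @rdname RegionalTimeSeries-class
#' @export
RegionalTimeSeries <- function(values, trSeconds, bandHz = NULL, labels = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(labels))
        labels <- if (!is.null(colnames(values))) colnames(values)
                  else paste0("R", seq_len(ncol(values)))
    colnames(values) <- labels
    new("RegionalTimeSeries", values = values, trSeconds = as.numeric(trSeconds),
        bandHz = if (is.null(bandHz)) numeric(0) else as.numeric(bandHz),
        labels = as.character(labels))
}

setMethod("show", "RegionalTimeSeries", function(object) {
    cat("RegionalTimeSeries:", nrow(object@values), "volumes x",
        ncol(object@values), "regions, TR =", object@trSeconds, "s\n")
    if (length(object@bandHz))
        cat("  band:", object@bandHz[1], "-", object@bandHz[2], "Hz\n")
    else cat("  band: unfiltered\n")
})

#' HopfParameters: parameters of the coupled Stuart-Landau network
#'
#' Parameters for a network of stochastic Hopf normal-form (Stuart-Landau)
#' oscillators. Each node n has bifurcation parameter \code{a[n]}
#' (dimensionless; a < 0 gives noise-driven damped oscillations, a > 0 a
#' limit cycle of radius sqrt(a)) and angular frequency
#' \code{omega[n] = 2*pi*f[n]} in rad/s. \code{beta} is the additive Gaussian
#' noise standard deviation.
#'
#' @slot a numeric N-vector of bifurcation parameters.
#' @slot omega numeric N-vector of angular frequencies (rad/s).
#' @slot beta noise standard deviation.
#' @slot dt Euler-Maruyama integration step (s).
#' @slot trSeconds output sampling period (s); must be a multiple of dt.
#' @slot durationSeconds simulated length after burn-in (s).
#' @slot burnInSeconds discarded initial transient (s).
#' @slot seed integer RNG seed.
#' @export
setClass("HopfParameters",
    representation(a = "numeric", omega = "numeric", beta = "numeric",
                   dt = "numeric", trSeconds = "numeric",
                   durationSeconds = "numeric", burnInSeconds = "numeric",
                   seed = "integer"))

setValidity("HopfParameters", function(object) {
    if (length(object@a) != length(object@omega))
        return("'a' and 'omega' must have the same length")
    if (object@beta < 0) return("'beta' must be >= 0")
    if (object@dt <= 0 || object@dt > object@trSeconds + 1e-12)
        return("'dt' must be positive and <= trSeconds")
    if (object@durationSeconds <= 0)
        return("'durationSeconds' must be positive")
    if (object@burnInSeconds < 0)
        return("'burnInSeconds' must be >= 0")
    TRUE
})

#' @param n number of nodes (used when \code{a}/\code{omega} are scalars).
#' @param a bifurcation parameter(s); recycled to length n. Default -0.02.
#' @param freqHz intrinsic frequency/frequencies in Hz (omega = 2*pi*freqHz).
#'   Default 0.05 Hz, in the infra-slow fMRI range.
#' @param beta noise SD, default 0.01.
#' @param dt integration step (s); defaults to the step closest to 0.1 s
#'   that divides \code{trSeconds} exactly, so every TR falls on a grid
#'   point.
#' @param trSeconds output sampling period (s), default 0.72.
#' @param durationSeconds simulated length after burn-in (s), default 360.
#' @param burnInSeconds discarded transient (s), default 100.
#' @param seed RNG seed.
#' @return A \code{HopfParameters} object.
#' @rdname HopfParameters-class
#' @export
HopfParameters <- function(n = NULL, a = -0.02, freqHz = 0.05, beta = 0.01,
                           dt = NULL, trSeconds = 0.72, durationSeconds = 360,
                           burnInSeconds = 100, seed = 1L) {
    if (!is.null(n)) {
        a <- rep_len(a, n)
        freqHz <- rep_len(freqHz, n)
    }
    if (is.null(dt)) dt <- trSeconds / max(1, round(trSeconds / 0.1))
    new("HopfParameters", a = as.numeric(a), omega = 2 * pi * as.numeric(freqHz),
        beta = as.numeric(beta), dt = as.numeric(dt),
        trSeconds = as.numeric(trSeconds),
        durationSeconds = as.numeric(durationSeconds),
        burnInSeconds = as.numeric(burnInSeconds), seed = as.integer(seed))
}

setMethod("show", "HopfParameters", function(object) {
    cat("HopfParameters:", length(object@a), "nodes | a in [",
        min(object@a), ",", max(object@a), "] | f in [",
        round(min(object@omega) / (2 * pi), 4), ",",
        round(max(object@omega) / (2 * pi), 4), "] Hz\n")
    cat("  beta =", object@beta, "| dt =", object@dt, "s | TR =",
        object@trSeconds, "s |", object@durationSeconds, "s after",
        object@burnInSeconds, "s burn-in | seed", object@seed, "\n")
})

#' FCStatistics: zero-lag and time-shifted correlation matrices
#'
#' Zero-lag Pearson correlations plus forward and time-reversed shifted
#' correlations at a fixed lag (in TRs). The forward entry (n, p) is
#' cor(x_n(t), x_p(t + lag)); the reversal entry is the same statistic on
#' the time-reversed series.
#'
#' @slot fc N x N symmetric zero-lag correlation matrix, unit diagonal.
#' @slot fcForward N x N lagged correlation matrix (generally asymmetric).
#' @slot fcReversal N x N lagged correlation of the reversed series.
#' @slot lagTRs lag in sampling periods.
#' @export
setClass("FCStatistics",
    representation(fc = "matrix", fcForward = "matrix",
                   fcReversal = "matrix", lagTRs = "integer"))

setValidity("FCStatistics", function(object) {
    n <- nrow(object@fc)
    for (nm in c("fc", "fcForward", "fcReversal")) {
        m <- slot(object, nm)
        if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
            return(sprintf("'%s' must be %d x %d", nm, n, n))
        if (any(!is.finite(m)) || max(abs(m)) > 1 + 1e-8)
            return(sprintf("'%s' entries must be finite correlations", nm))
    }
    if (max(abs(object@fc - t(object@fc))) > 1e-8)
        return("'fc' must be symmetric")
    if (max(abs(diag(object@fc) - 1)) > 1e-8)
        return("'fc' must have unit diagonal")
    if (object@lagTRs < 1L) return("'lagTRs' must be >= 1")
    TRUE
})

setMethod("show", "FCStatistics", function(object) {
    cat("FCStatistics:", nrow(object@fc), "regions, lag =", object@lagTRs,
        "TR\n")
    ut <- upper.tri(object@fc)
    cat("  mean |FC| =", round(mean(abs(object@fc[ut])), 4),
        "| mean forward-reversal asymmetry =",
        round(mean(abs(object@fcForward - object@fcReversal)), 4), "\n")
})

#' GECResult: a fitted generative effective connectivity matrix
#'
#' The signed effective connectivity fitted by the heuristic gradient update,
#' together with the update mask (the known anatomical support), the fit
#' trajectory, and the learning rates used.
#'
#' @slot gec N x N signed coupling matrix (zero outside \code{mask}).
#' @slot allowNegative if FALSE, entries were clamped at zero from below
#'   (cooperative-only variant).
#' @slot mask N x N logical matrix of updatable entries.
#' @slot fitHistory data.frame with columns \code{iteration} and
#'   \code{fcCorrelation} (empirical-vs-simulated FC correlation per
#'   iteration).
#' @slot epsilon learning rate on the zero-lag FC error.
#' @slot epsilonPrime learning rate on the forward-minus-reversal error.
#' @slot converged logical.
#' @slot seed integer seed used for the per-iteration simulations.
#' @export
setClass("GECResult",
    representation(gec = "matrix", allowNegative = "logical",
                   mask = "matrix", fitHistory = "data.frame",
                   epsilon = "numeric", epsilonPrime = "numeric",
                   converged = "logical", seed = "integer"))

setValidity("GECResult", function(object) {
    if (any(object@gec[!object@mask] != 0))
        return("'gec' must be zero outside 'mask'")
    if (!object@allowNegative && any(object@gec < 0))
        return("cooperative-only GEC must be elementwise >= 0")
    if (nrow(object@fitHistory) < 1L)
        return("'fitHistory' must be non-empty")
    TRUE
})

setMethod("show", "GECResult", function(object) {
    cat("GECResult:", nrow(object@gec), "regions,",
        sum(object@mask), "masked entries,",
        if (object@allowNegative) "cooperative+competitive"
        else "cooperative-only", "\n")
    cat("  final fit r =",
        round(object@fitHistory$fcCorrelation[nrow(object@fitHistory)], 4),
        "| best fit r =", round(max(object@fitHistory$fcCorrelation), 4),
        "| converged:", object@converged, "\n")
    if (object@allowNegative)
        cat("  negative edge fraction =",
            round(negativeEdgeFraction(object), 4), "\n")
})

#' PhiIDAtoms: the 16 atoms of Gaussian MMI integrated information
#' decomposition
#'
#' Atoms of the minimum-mutual-information integrated information
#' decomposition (MMI-PhiID) of the time-delayed mutual information between
#' two processes. Atoms are indexed "past->future" over the four antichains
#' of two sources: \code{rr} = \{1\}\{2\} (redundant), \code{x} = \{1\},
#' \code{y} = \{2\}, \code{s} = \{12\} (synergistic); e.g. \code{"s->s"} is
#' temporally persistent synergy and \code{"rr->rr"} persistent redundancy.
#'
#' @slot atoms named numeric vector of 16 atoms (nats).
#' @slot tdmi time-delayed mutual information I(past; future) in nats.
#' @slot tauTRs lag in sampling periods.
#' @slot pair integer pair of region indices (0 when not applicable).
#' @export
setClass("PhiIDAtoms",
    representation(atoms = "numeric", tdmi = "numeric", tauTRs = "integer",
                   pair = "integer"),
    prototype(pair = c(0L, 0L)))

setValidity("PhiIDAtoms", function(object) {
    if (length(object@atoms) != 16L || is.null(names(object@atoms)))
        return("'atoms' must be a named numeric of length 16")
    if (abs(sum(object@atoms) - object@tdmi) > 1e-8)
        return("atoms must sum to the time-delayed mutual information")
    TRUE
})

setMethod("show", "PhiIDAtoms", function(object) {
    cat("PhiIDAtoms (MMI, nats): tdmi =", round(object@tdmi, 5),
        "at lag", object@tauTRs, "TR\n")
    cat("  persistent synergy (s->s)  =", round(object@atoms[["s->s"]], 5), "\n")
    cat("  persistent redundancy (rr->rr) =",
        round(object@atoms[["rr->rr"]], 5), "\n")
})
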