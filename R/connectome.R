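#' Symmetrize a connectome
#'
#' Replaces the weight matrix by \code{(G + t(G)) / 2} and marks the result
#' undirected. Used to place tract-tracing (directed) connectomes on the same
#' footing as tractography-derived ones, letting the generative model itself
#' determine any asymmetry.
#'
#' @param sc a \code{StructuralConnectome}.
#' @return An undirected \code{StructuralConnectome}.
#' @examples
#' sc <- StructuralConnectome(matrix(c(0, 0, 2, 0), 2), directed = TRUE)
#' weights(symmetrizeConnectome(sc))
#' @export
symmetrizeConnectome <- function(sc) {
    w <- (weights(sc) + t(weights(sc))) / 2
    initialize(sc, weights = w, directed = FALSE)
}

#' Threshold a connectome to a target edge density
#'
#' Keeps the top \code{ceiling(density * E)} off-diagonal edges by absolute
#' weight, where E = N(N-1)/2 is the number of upper-triangle edge slots, and
#' sets the rest to zero (symmetric removal). If the connectome already has
#' fewer nonzero edges than the target count it is returned unchanged, which
#' makes the operation idempotent at a fixed density.
#'
#' @param sc an undirected \code{StructuralConnectome}.
#' @param density target fraction of retained edge slots, in (0, 1].
#' @return A \code{StructuralConnectome} at (at most) the requested density.
#' @export
thresholdDensity <- function(sc, density) {
    if (isDirected(sc)) stop("thresholdDensity expects an undirected connectome")
    if (length(density) != 1L || !is.finite(density) ||
        density <= 0 || density > 1)
        stop("'density' must be in (0, 1]")
    w <- weights(sc)
    n <- nrow(w)
    ut <- which(upper.tri(w))
    k <- ceiling(density * length(ut))
    nz <- ut[w[ut] != 0]
    if (length(nz) > k) {
        ord <- nz[order(abs(w[nz]), decreasing = TRUE)]
        drop <- ord[-seq_len(k)]
        w[drop] <- 0
        w[lower.tri(w)] <- t(w)[lower.tri(w)]
    }
    initialize(sc, weights = w)
}

#' Rescale coupling strength to a target maximum
#'
#' Rescales all weights linearly so that \code{max(abs(weights))} equals
#' \code{targetMax}. The default 0.2 keeps the coupled Hopf network below
#' full synchrony at the default bifurcation parameter a = -0.02.
#'
#' @param sc a \code{StructuralConnectome} with at least one nonzero weight.
#' @param targetMax target maximum absolute weight (default 0.2).
#' @return A rescaled \code{StructuralConnectome}.
#' @export
scaleCoupling <- function(sc, targetMax = 0.2) {
    w <- weights(sc)
    m <- max(abs(w))
    if (m == 0) stop("cannot rescale an all-zero connectome")
    initialize(sc, weights = w * (targetMax / m))
}
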