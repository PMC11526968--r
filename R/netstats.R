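#' Newman spectral modularity of a nonnegative graph
#'
#' Community detection by Newman's leading-eigenvector (spectral) method on
#' a symmetric nonnegative weighted graph, as implemented in
#' \code{igraph::cluster_leading_eigen}, with the modularity Q of the
#' returned partition.
#'
#' @param adjacency symmetric nonnegative N x N matrix (zero diagonal).
#' @return A list with \code{membership} (integer N-vector) and \code{q}.
#' @export
networkModularity <- function(adjacency) {
    if (any(adjacency < 0)) stop("adjacency must be nonnegative")
    if (max(abs(adjacency - t(adjacency))) > 1e-10)
        stop("adjacency must be symmetric")
    if (all(adjacency == 0)) stop("empty graph")
    g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cl <- igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
    list(membership = as.integer(igraph::membership(cl)),
         q = igraph::modularity(g, igraph::membership(cl),
                                weights = igraph::E(g)$weight))
}

#' Binary clustering coefficient
#'
#' Topological (binarized at nonzero) clustering coefficient
#' \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with \eqn{t_i} the number of
#' triangles around node i and \eqn{k_i} its degree; nodes of degree < 2
#' get \eqn{C_i = 0}.
#'
#' @param adjacency symmetric N x N matrix; edges are nonzero entries.
#' @return A list with \code{perNode} (N-vector) and \code{mean}.
#' @export
clusteringCoefficient <- function(adjacency) {
    if (max(abs(abs(adjacency) - t(abs(adjacency)))) > 1e-10)
        stop("adjacency must be symmetric")
    b <- (adjacency != 0) * 1
    diag(b) <- 0
    g <- igraph::graph_from_adjacency_matrix(b, mode = "undirected")
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    ci[!is.finite(ci)] <- 0
    list(perNode = ci, mean = mean(ci))
}

#' Summary statistics of positive versus negative GEC edges
#'
#' Splits the masked edges of a fitted GEC by sign and contrasts the two
#' edge classes: fraction negative, mean absolute weight, mean Euclidean
#' inter-centroid length (when coordinates are given), and the modularity
#' and mean clustering coefficient of each sign-class graph (on absolute
#' weights; clustering on the binarized graph). An asymmetric GEC is
#' symmetrized by averaging first.
#'
#' @param gec a \code{GECResult}.
#' @param coords optional N x 3 region centroid matrix (mm) for the length
#'   statistics.
#' @return A list with fields \code{fractionNegative},
#'   \code{meanAbsWeightPos}, \code{meanAbsWeightNeg}, \code{meanLengthPos},
#'   \code{meanLengthNeg}, \code{modularityPos}, \code{modularityNeg},
#'   \code{clusteringPos}, \code{clusteringNeg}. Negative-side fields are
#'   \code{NULL} when no negative edges exist.
#' @export
signedEdgeSummary <- function(gec, coords = NULL) {
    w <- gecMatrix(gec)
    mask <- updateMask(gec)
    if (max(abs(w - t(w))) > 1e-12) {
        message("signedEdgeSummary: asymmetric GEC symmetrized by averaging")
        w <- (w + t(w)) / 2
        mask <- mask | t(mask)
    }
    ut <- upper.tri(w) & mask
    wPos <- w * (w > 0)
    wNeg <- -w * (w < 0)      # absolute weights of the negative class
    pos <- ut & w > 0
    neg <- ut & w < 0
    out <- list(fractionNegative = sum(neg) / sum(ut & w != 0))
    out$meanAbsWeightPos <- if (any(pos)) mean(w[pos]) else NULL
    out$meanAbsWeightNeg <- if (any(neg)) mean(-w[neg]) else NULL
    if (!is.null(coords)) {
        dmat <- as.matrix(stats::dist(coords))
        out$meanLengthPos <- if (any(pos)) mean(dmat[pos]) else NULL
        out$meanLengthNeg <- if (any(neg)) mean(dmat[neg]) else NULL
    }
    if (any(pos)) {
        out$modularityPos <- networkModularity(wPos)$q
        out$clusteringPos <- clusteringCoefficient(wPos)$mean
    }
    if (any(neg)) {
        out$modularityNeg <- networkModularity(wNeg)$q
        out$clusteringNeg <- clusteringCoefficient(wNeg)$mean
    }
    out
}
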