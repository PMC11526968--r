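#' Generate a ground-truth signed connectome
#'
#' Builds a synthetic signed coupling matrix with the structure the
#' empirical signed effective connectomes show: dense, strong positive
#' edges within spatially localized modules plus sparse weaker positive
#' edges between modules, and weak, long-range, diffuse negative edges
#' placed preferentially on the most distant cross-module pairs. The
#' realized negative-edge fraction equals the requested one by
#' construction; the matrix is symmetric with zero diagonal.
#'
#' @param nRegions number of regions N (default 30).
#' @param nModules number of modules (default 3; balanced membership).
#' @param fractionNegative fraction of edges that are negative (default 0.3,
#'   inside the empirically observed 25-40\% envelope).
#' @param posWeightRange range of positive within-module weights
#'   (default \code{c(0.5, 1)}); between-module positive weights are 0.3x.
#' @param negWeightScale negative magnitudes as a multiple of the positive
#'   scale (default 0.5: negatives are weaker).
#' @param negMinDistanceQuantile negative edges are drawn from cross-module
#'   pairs above this distance quantile (default 0.6, i.e. the top 40\%
#'   of distances: negatives are long-range).
#' @param density fraction of the N(N-1)/2 edge slots occupied
#'   (default 0.3).
#' @param geometry \code{"cube"} (modules clustered in a 100 mm cube) or
#'   \code{"ring"} (modules as arcs on a circle).
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @return A list with \code{connectome} (a signed, undirected
#'   \code{\link{StructuralConnectome}} with coordinates) and \code{modules}
#'   (integer membership N-vector).
#' @export
makeGroundTruth <- function(nRegions = 30L, nModules = 3L,
                            fractionNegative = 0.3,
                            posWeightRange = c(0.5, 1),
                            negWeightScale = 0.5,
                            negMinDistanceQuantile = 0.6,
                            density = 0.3,
                            geometry = c("cube", "ring"), seed = 1L) {
    geometry <- match.arg(geometry)
    if (fractionNegative < 0 || fractionNegative >= 1)
        stop("'fractionNegative' must be in [0, 1)")
    if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
    n <- as.integer(nRegions)
    modules <- sort(rep_len(seq_len(nModules), n))
    with_seed(seed, {
        if (geometry == "cube") {
            centers <- matrix(stats::runif(nModules * 3, 10, 90), nModules, 3)
            coords <- centers[modules, ] +
                matrix(stats::rnorm(n * 3, sd = 8), n, 3)
        } else {
            theta <- 2 * pi * (seq_len(n) - 1) / n
            coords <- cbind(50 * cos(theta), 50 * sin(theta), 0) +
                matrix(stats::rnorm(n * 3, sd = 2), n, 3)
        }
        dmat <- as.matrix(stats::dist(coords))
        ut <- which(upper.tri(dmat))
        nEdges <- ceiling(density * length(ut))
        nNeg <- round(fractionNegative * nEdges)
        nPos <- nEdges - nNeg
        sameModule <- outer(modules, modules, `==`)
        cross <- ut[!sameModule[ut]]
        within <- ut[sameModule[ut]]
        thr <- stats::quantile(dmat[ut], negMinDistanceQuantile)
        negCand <- cross[dmat[cross] >= thr]
        if (length(negCand) < nNeg)
            stop("infeasible: only ", length(negCand),
                 " long-range cross-module slots for ", nNeg,
                 " negative edges; lower fractionNegative or ",
                 "negMinDistanceQuantile")
        negIdx <- sample(negCand, nNeg)
        nPosW <- min(length(within), round(0.85 * nPos))
        posW <- sample(within, nPosW)
        crossLeft <- setdiff(cross, negIdx)
        # remaining positive edges: short-range cross-module
        crossLeft <- crossLeft[order(dmat[crossLeft])]
        nPosB <- nPos - nPosW
        if (nPosB > length(crossLeft))
            stop("infeasible: not enough cross-module slots for the ",
                 "requested density")
        posB <- crossLeft[seq_len(nPosB)]
        w <- matrix(0, n, n)
        w[posW] <- stats::runif(nPosW, posWeightRange[1], posWeightRange[2])
        w[posB] <- 0.3 * stats::runif(nPosB, posWeightRange[1],
                                      posWeightRange[2])
        w[negIdx] <- -negWeightScale *
            stats::runif(nNeg, posWeightRange[1], posWeightRange[2])
        w[lower.tri(w)] <- t(w)[lower.tri(w)]
        sc <- StructuralConnectome(w, coords = coords, directed = FALSE,
                                   speciesTag = "synthetic")
        list(connectome = sc, modules = modules)
    })
}

.species_presets <- list(
    human = list(trSeconds = 0.72, bandHz = c(0.008, 0.09)),
    macaque = list(trSeconds = 2.6, bandHz = c(0.008, 0.09)),
    mouse = list(trSeconds = 1.0, bandHz = c(0.01, 0.1)))

#' Generate a synthetic cohort of simulated BOLD recordings
#'
#' From a ground-truth signed connectome, draws per-subject couplings by
#' multiplicative lognormal jitter on the edge magnitudes (sign-preserving,
#' so subject individuality never flips an interaction type), simulates
#' coupled-Hopf BOLD for each subject at a species-like TR, and band-pass
#' filters the result. Region roles ("visual" = module 1, "somatomotor" =
#' module 2) and a cognitive map bank (module-indicator maps plus spatially
#' smoothed random patterns) are attached so every downstream analysis can
#' run without external data.
#'
#' @param groundTruth output of \code{\link{makeGroundTruth}}.
#' @param nSubjects number of subjects (default 3).
#' @param subjectJitterSD SD of the lognormal magnitude jitter (default 0.1;
#'   0 makes subjects identical up to noise seed).
#' @param species \code{"human"} (TR 0.72 s, band 0.008-0.09 Hz),
#'   \code{"macaque"} (TR 2.6 s) or \code{"mouse"} (TR 1.0 s, band
#'   0.01-0.1 Hz).
#' @param nVolumes volumes per subject (default 300).
#' @param couplingMax maximum absolute coupling after rescaling, or
#'   \code{"auto"} (default): the largest scale, capped at 0.2, that keeps
#'   the linearized network comfortably stable (spectral abscissa at
#'   \code{stabilityMargin} of the node decay rate \code{|a|}), so both the
#'   stochastic simulation stays in the subthreshold regime and the
#'   deterministic fitting engine is usable.
#' @param stabilityMargin retained fraction of the node decay rate under
#'   \code{couplingMax = "auto"} (default 0.25).
#' @param nMaps number of random maps added to the module-indicator maps in
#'   the bank (default 17, giving 20 maps at 3 modules).
#' @param params optional \code{HopfParameters} template; frequencies
#'   default to per-node draws in 0.04-0.07 Hz.
#' @param seed master seed.
#' @return A list of class \code{"SyntheticCohort"}: \code{groundTruth}
#'   (the rescaled signed connectome), \code{modules}, \code{subjects}
#'   (each with \code{coupling}, \code{ts}, \code{meta}), \code{roles},
#'   \code{mapBank}, \code{trSeconds}, \code{bandHz}, \code{params},
#'   \code{seed}.
#' @export
makeCohort <- function(groundTruth, nSubjects = 3L, subjectJitterSD = 0.1,
                       species = c("human", "macaque", "mouse"),
                       nVolumes = 300L, couplingMax = "auto", nMaps = 17L,
                       params = NULL, stabilityMargin = 0.25, seed = 1L) {
    species <- match.arg(species)
    preset <- .species_presets[[species]]
    n <- nrow(weights(groundTruth$connectome))
    modules <- groundTruth$modules
    seeds <- child_seeds(seed, 2L * nSubjects + 2L)
    if (is.null(params)) {
        freqs <- with_seed(seeds[2 * nSubjects + 1],
                           stats::runif(n, 0.04, 0.07))
        params <- HopfParameters(n = n, freqHz = freqs,
                                 trSeconds = preset$trSeconds,
                                 durationSeconds = nVolumes *
                                     preset$trSeconds + 1)
    }
    if (identical(couplingMax, "auto")) {
        w <- weights(groundTruth$connectome)
        gc <- w
        diag(gc) <- diag(gc) - rowSums(w)
        mu <- max(Re(eigen(gc, only.values = TRUE)$values))
        aDecay <- max(1e-6, -max(params@a))
        couplingMax <- if (mu <= 0) 0.2
            else min(0.2, (1 - stabilityMargin) * aDecay / mu * max(abs(w)))
    }
    sc <- scaleCoupling(groundTruth$connectome, couplingMax)
    g0 <- weights(sc)
    ok <- tryCatch({linearizedCovariance(g0, params, params@trSeconds); TRUE},
                   error = function(e) FALSE)
    if (!ok)
        stop("simulation unstable at the requested coupling; ",
             "reduce couplingMax or edge weights")
    subjects <- vector("list", nSubjects)
    for (s in seq_len(nSubjects)) {
        jit <- with_seed(seeds[2 * s - 1], {
            j <- matrix(exp(stats::rnorm(n * n, sd = subjectJitterSD)), n, n)
            j[lower.tri(j)] <- t(j)[lower.tri(j)]
            j
        })
        gS <- g0 * jit
        p <- initialize(params, seed = seeds[2 * s])
        sim <- simulateHopf(gS, p)
        ts <- bandpassFilter(sim$ts, preset$bandHz[1], preset$bandHz[2])
        subjects[[s]] <- list(
            coupling = gS, ts = ts,
            meta = list(subject_id = sprintf("sub-%02d", s),
                        tr_seconds = preset$trSeconds,
                        n_volumes = nrow(signalMatrix(ts)),
                        band_hz = preset$bandHz, seed = seeds[2 * s]))
    }
    mapBank <- with_seed(seeds[2 * nSubjects + 2], {
        ind <- vapply(seq_len(max(modules)),
                      function(m) as.numeric(modules == m), numeric(n))
        dmat <- as.matrix(stats::dist(regionCoords(sc)))
        smoother <- exp(-dmat / 20)
        rnd <- smoother %*% matrix(stats::rnorm(n * nMaps), n, nMaps)
        bank <- cbind(ind, scale(rnd))
        colnames(bank) <- c(paste0("module", seq_len(ncol(ind))),
                            paste0("pattern", seq_len(nMaps)))
        bank
    })
    structure(list(groundTruth = sc, modules = modules, subjects = subjects,
                   roles = list(visual = which(modules == 1L),
                                somatomotor = which(modules == 2L)),
                   mapBank = mapBank, trSeconds = preset$trSeconds,
                   bandHz = preset$bandHz, params = params,
                   seed = as.integer(seed)),
              class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
    cat("SyntheticCohort:", length(x$subjects), "subjects,",
        nrow(weights(x$groundTruth)), "regions, TR =", x$trSeconds, "s\n")
    w <- weights(x$groundTruth)
    e <- w[upper.tri(w)]
    e <- e[e != 0]
    cat("  ground-truth negative edge fraction:",
        round(mean(e < 0), 3), "\n")
    invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Layout: \code{ground_truth.csv} + \code{labels.txt} + \code{coords.csv},
#' per-subject \code{sub-XX_ts.tsv} / \code{sub-XX_meta.yaml} /
#' \code{sub-XX_coupling.csv}, role files \code{visual.txt} /
#' \code{somatomotor.txt}, \code{map_bank.csv} and a \code{cohort.yaml}
#' manifest.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(dir, ...)
    writeConnectome(cohort$groundTruth, fp("ground_truth.csv"),
                    labelsPath = fp("labels.txt"),
                    coordsPath = fp("coords.csv"))
    labels <- regionLabels(cohort$groundTruth)
    for (s in seq_along(cohort$subjects)) {
        sub <- cohort$subjects[[s]]
        id <- sub$meta$subject_id
        writeTimeSeries(sub$ts, fp(paste0(id, "_ts.tsv")),
                        metaPath = fp(paste0(id, "_meta.yaml")))
        writeConnectome(StructuralConnectome(sub$coupling, labels = labels),
                        fp(paste0(id, "_coupling.csv")))
    }
    writeLines(labels[cohort$roles$visual], fp("visual.txt"))
    writeLines(labels[cohort$roles$somatomotor], fp("somatomotor.txt"))
    utils::write.csv(cohort$mapBank, fp("map_bank.csv"), row.names = FALSE)
    yaml::write_yaml(list(n_subjects = length(cohort$subjects),
                          tr_seconds = cohort$trSeconds,
                          band_hz = as.list(cohort$bandHz),
                          modules = as.list(as.integer(cohort$modules)),
                          seed = cohort$seed),
                     fp("cohort.yaml"))
    invisible(dir)
}

#' Read a cohort directory written by \code{writeCohort}
#'
#' @param dir cohort directory.
#' @return A \code{SyntheticCohort}-shaped list (without \code{params}).
#' @export
readCohort <- function(dir) {
    fp <- function(...) file.path(dir, ...)
    manifest <- yaml::read_yaml(fp("cohort.yaml"))
    gt <- readConnectome(fp("ground_truth.csv"), labelsPath = fp("labels.txt"),
                         coordsPath = fp("coords.csv"),
                         speciesTag = "synthetic")
    labels <- regionLabels(gt)
    subjects <- lapply(seq_len(manifest$n_subjects), function(s) {
        id <- sprintf("sub-%02d", s)
        ts <- readTimeSeries(fp(paste0(id, "_ts.tsv")),
                             metaPath = fp(paste0(id, "_meta.yaml")))
        coupling <- weights(readConnectome(fp(paste0(id, "_coupling.csv"))))
        list(coupling = coupling, ts = ts,
             meta = list(subject_id = id, tr_seconds = trSeconds(ts)))
    })
    modules <- as.integer(unlist(manifest$modules))
    structure(list(groundTruth = gt, modules = modules, subjects = subjects,
                   roles = list(visual = match(readLines(fp("visual.txt")),
                                               labels),
                                somatomotor = match(
                                    readLines(fp("somatomotor.txt")), labels)),
                   mapBank = as.matrix(utils::read.csv(fp("map_bank.csv"))),
                   trSeconds = manifest$tr_seconds,
                   bandHz = as.numeric(unlist(manifest$band_hz)),
                   params = NULL, seed = manifest$seed),
              class = "SyntheticCohort")
}
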