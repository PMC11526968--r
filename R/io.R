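#' Read a structural connectome from a dense CSV matrix
#'
#' Reads an N x N numeric CSV (header row optional), an optional sidecar
#' label file (one region name per line) and optional centroid coordinates
#' (CSV with columns \code{label,x,y,z} in mm). A nonzero diagonal is forced
#' to zero with a message; directedness is inferred from matrix asymmetry.
#'
#' @param path path to the dense CSV weight matrix.
#' @param labelsPath optional path to a one-label-per-line text file.
#' @param coordsPath optional path to a \code{label,x,y,z} CSV.
#' @param speciesTag free-text provenance tag stored on the object.
#' @return A \code{\link{StructuralConnectome}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.table(matrix(0, 3, 3), f, sep = ",", row.names = FALSE,
#'             col.names = FALSE)
#' readConnectome(f)
#' @export
readConnectome <- function(path, labelsPath = NULL, coordsPath = NULL,
                           speciesTag = "unspecified") {
    first <- strsplit(readLines(path, n = 1L), ",")[[1]]
    hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
    df <- utils::read.csv(path, header = hasHeader, check.names = FALSE)
    w <- as.matrix(df)
    if (!is.numeric(w)) stop("connectome CSV contains non-numeric cells")
    if (nrow(w) != ncol(w))
        stop(sprintf("connectome must be square; got %d x %d",
                     nrow(w), ncol(w)))
    labels <- if (!is.null(labelsPath)) {
        lab <- readLines(labelsPath)
        lab <- lab[nzchar(trimws(lab))]
        if (length(lab) != nrow(w))
            stop(sprintf("label count (%d) does not match matrix size (%d)",
                         length(lab), nrow(w)))
        trimws(lab)
    } else if (hasHeader) colnames(df) else NULL
    if (any(diag(w) != 0)) {
        message("readConnectome: nonzero diagonal forced to zero")
        diag(w) <- 0
    }
    coords <- NULL
    if (!is.null(coordsPath)) {
        cdf <- utils::read.csv(coordsPath)
        need <- c("label", "x", "y", "z")
        if (!all(need %in% names(cdf)))
            stop("coords CSV must have columns label,x,y,z")
        if (!is.null(labels)) {
            idx <- match(labels, cdf$label)
            if (anyNA(idx)) stop("coords missing for some labels")
            cdf <- cdf[idx, ]
        }
        coords <- as.matrix(cdf[, c("x", "y", "z")])
    }
    StructuralConnectome(w, labels = labels, coords = coords,
                         speciesTag = speciesTag)
}

#' Write a structural connectome as CSV (full-precision text)
#'
#' @param sc a \code{StructuralConnectome}.
#' @param path output CSV path (no header; values at 15 significant digits).
#' @param labelsPath optional path for the sidecar label file.
#' @param coordsPath optional path for a \code{label,x,y,z} coordinates CSV.
#' @return \code{path}, invisibly.
#' @export
writeConnectome <- function(sc, path, labelsPath = NULL, coordsPath = NULL) {
    w <- weights(sc)
    txt <- apply(w, 1, function(r)
        paste(formatC(r, digits = 15, format = "g"), collapse = ","))
    writeLines(txt, path)
    if (!is.null(labelsPath)) writeLines(regionLabels(sc), labelsPath)
    if (!is.null(coordsPath)) {
        xyz <- regionCoords(sc)
        if (!nrow(xyz)) stop("connectome has no coordinates to write")
        utils::write.csv(data.frame(label = regionLabels(sc), x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3]),
                         coordsPath, row.names = FALSE)
    }
    invisible(path)
}

#' Read regional time series from TSV
#'
#' Reads a T x N tab-separated table (header row = region labels). The
#' sampling period can come from \code{trSeconds} or from a sidecar YAML
#' file with fields \code{tr_seconds} and optionally \code{band_hz}.
#'
#' @param path TSV path (T rows x N columns, header = labels).
#' @param trSeconds sampling period (s); overrides the sidecar.
#' @param metaPath optional YAML sidecar (fields \code{tr_seconds},
#'   \code{band_hz}).
#' @return A \code{\link{RegionalTimeSeries}}.
#' @export
readTimeSeries <- function(path, trSeconds = NULL, metaPath = NULL) {
    df <- utils::read.delim(path, check.names = FALSE)
    v <- as.matrix(df)
    if (!is.numeric(v) || anyNA(v))
        stop("time-series TSV must be fully numeric with no missing values")
    band <- NULL
    if (!is.null(metaPath)) {
        meta <- yaml::read_yaml(metaPath)
        trSeconds <- trSeconds %||% meta$tr_seconds
        band <- meta$band_hz
    }
    if (is.null(trSeconds))
        stop("sampling period unknown: give trSeconds or a metaPath sidecar")
    RegionalTimeSeries(v, trSeconds = trSeconds, bandHz = band,
                       labels = colnames(df))
}

#' Write regional time series as TSV (plus optional YAML sidecar)
#'
#' @param ts a \code{RegionalTimeSeries}.
#' @param path output TSV path.
#' @param metaPath optional YAML sidecar path recording \code{tr_seconds},
#'   \code{n_volumes} and \code{band_hz}.
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(ts, path, metaPath = NULL) {
    v <- signalMatrix(ts)
    header <- paste(regionLabels(ts), collapse = "\t")
    body <- apply(v, 1, function(r)
        paste(formatC(r, digits = 15, format = "g"), collapse = "\t"))
    writeLines(c(header, body), path)
    if (!is.null(metaPath)) {
        meta <- list(tr_seconds = trSeconds(ts), n_volumes = nrow(v))
        if (length(bandHz(ts))) meta$band_hz <- as.list(bandHz(ts))
        yaml::write_yaml(meta, metaPath)
    }
    invisible(path)
}
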