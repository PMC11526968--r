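#' Accessors for gecnet classes
#'
#' Small accessor generics: \code{weights} returns the coupling matrix of a
#' \code{StructuralConnectome}, \code{regionLabels} the region names,
#' \code{regionCoords} the N x 3 centroid matrix, \code{signalMatrix} the
#' T x N values of a \code{RegionalTimeSeries}, \code{trSeconds} its sampling
#' period and \code{bandHz} its filter band, \code{gecMatrix} the fitted
#' coupling of a \code{GECResult}, \code{fitHistory} its fit trajectory,
#' \code{atoms} the 16 information atoms of a \code{PhiIDAtoms}.
#'
#' @param object a gecnet S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("weights", function(object) standardGeneric("weights"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionCoords", function(object) standardGeneric("regionCoords"))
#' @rdname accessors
#' @export
setGeneric("isDirected", function(object) standardGeneric("isDirected"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("bandHz", function(object) standardGeneric("bandHz"))
#' @rdname accessors
#' @export
setGeneric("gecMatrix", function(object) standardGeneric("gecMatrix"))
#' @rdname accessors
#' @export
setGeneric("fitHistory", function(object) standardGeneric("fitHistory"))
#' @rdname accessors
#' @export
setGeneric("updateMask", function(object) standardGeneric("updateMask"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("tdmi", function(object) standardGeneric("tdmi"))
#' @rdname accessors
#' @export
setGeneric("synergyPersistent", function(object) standardGeneric("synergyPersistent"))
#' @rdname accessors
#' @export
setGeneric("redundancyPersistent", function(object) standardGeneric("redundancyPersistent"))

#' @rdname accessors
#' @export
setMethod("weights", "StructuralConnectome", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("regionLabels", "StructuralConnectome", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionalTimeSeries", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("regionCoords", "StructuralConnectome", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("isDirected", "StructuralConnectome", function(object) object@directed)
#' @rdname accessors
#' @export
setMethod("signalMatrix", "RegionalTimeSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("trSeconds", "RegionalTimeSeries", function(object) object@trSeconds)
#' @rdname accessors
#' @export
setMethod("bandHz", "RegionalTimeSeries", function(object) object@bandHz)
#' @rdname accessors
#' @export
setMethod("gecMatrix", "GECResult", function(object) object@gec)
#' @rdname accessors
#' @export
setMethod("fitHistory", "GECResult", function(object) object@fitHistory)
#' @rdname accessors
#' @export
setMethod("updateMask", "GECResult", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("atoms", "PhiIDAtoms", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("tdmi", "PhiIDAtoms", function(object) object@tdmi)
#' @rdname accessors
#' @export
setMethod("synergyPersistent", "PhiIDAtoms", function(object) object@atoms[["s->s"]])
#' @rdname accessors
#' @export
setMethod("redundancyPersistent", "PhiIDAtoms", function(object) object@atoms[["rr->rr"]])
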