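#' @rdname accessors
#' @export
setGeneric("obsIds", function(x) standardGeneric("obsIds"))

#' @rdname accessors
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname accessors
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))

#' @rdname accessors
#' @export
setGeneric("labelLevels", function(x) standardGeneric("labelLevels"))

#' @rdname accessors
#' @export
setGeneric("methodId", function(x) standardGeneric("methodId"))

#' @rdname accessors
#' @export
setGeneric("configId", function(x) standardGeneric("configId"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("droppedObservations",
           function(x) standardGeneric("droppedObservations"))

#' @rdname accessors
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))

#' @rdname accessors
#' @export
setGeneric("agreementValues", function(x) standardGeneric("agreementValues"))

#' @rdname accessors
#' @export
setGeneric("consensusLabels", function(x) standardGeneric("consensusLabels"))

#' @rdname accessors
#' @export
setGeneric("consensusWeights", function(x) standardGeneric("consensusWeights"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("keptColumns", function(x) standardGeneric("keptColumns"))

#' @rdname accessors
#' @export
setGeneric("removedColumns", function(x) standardGeneric("removedColumns"))

#' @rdname accessors
#' @export
setGeneric("blockAssignments", function(x) standardGeneric("blockAssignments"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("neighborIndices", function(x) standardGeneric("neighborIndices"))

#' @rdname accessors
#' @export
setGeneric("neighborDistances",
           function(x) standardGeneric("neighborDistances"))

#' @rdname accessors
#' @export
setGeneric("meanCme", function(x) standardGeneric("meanCme"))
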