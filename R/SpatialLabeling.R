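#' Construct a SpatialLabeling
#'
#' @param obsIds character vector of unique observation ids.
#' @param coords numeric matrix or data.frame with two columns (x, y).
#' @param labels vector of categorical labels (character, factor or
#'   integer); recoded internally to dense integer codes.
#' @param methodId,configId,sampleId provenance strings.
#'
#' @return A \linkS4class{SpatialLabeling}.
#' @examples
#' sl <- SpatialLabeling(c("a", "b", "c"),
#'                       cbind(x = c(0, 1, 2), y = 0),
#'                       c("L1", "L1", "L2"))
#' labelLevels(sl)
#' @export
SpatialLabeling <- function(obsIds, coords, labels,
                            methodId = "unknown", configId = "default",
                            sampleId = NA_character_) {
  obsIds <- as.character(obsIds)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  rownames(coords) <- obsIds
  f <- factor(labels)
  new("SpatialLabeling",
      obsIds = obsIds, coords = coords,
      labels = as.integer(f), labelLevels = levels(f),
      methodId = as.character(methodId), configId = as.character(configId),
      sampleId = if (length(sampleId)) as.character(sampleId)
                 else NA_character_)
}

#' @rdname accessors
#' @param x an object of one of the package's classes.
#' @export
setMethod("obsIds", "SpatialLabeling", function(x) x@obsIds)

#' @rdname accessors
#' @export
setMethod("spatialCoords", "SpatialLabeling", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("labelCodes", "SpatialLabeling", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("labelLevels", "SpatialLabeling", function(x) x@labelLevels)

#' @rdname accessors
#' @export
setMethod("methodId", "SpatialLabeling", function(x) x@methodId)

#' @rdname accessors
#' @export
setMethod("configId", "SpatialLabeling", function(x) x@configId)

#' @rdname accessors
#' @export
setMethod("sampleId", "SpatialLabeling", function(x) x@sampleId)

setMethod("show", "SpatialLabeling", function(object) {
  cat(sprintf("SpatialLabeling: %d observations, %d labels\n",
              length(object@obsIds), length(object@labelLevels)))
  cat(sprintf("  method: %s | config: %s | sample: %s\n",
              object@methodId, object@configId, object@sampleId))
})

#' @rdname accessors
#' @export
setMethod("obsIds", "LabelingCollection", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("spatialCoords", "LabelingCollection", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  m <- cbind(x = rd$x, y = rd$y)
  rownames(m) <- rownames(x)
  m
})

#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabelingCollection",
          function(x) SummarizedExperiment::assay(x, "labels"))

#' @rdname accessors
#' @export
setMethod("provenance", "LabelingCollection", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(column = colnames(x),
             methodId = cd$methodId, configId = cd$configId,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("droppedObservations", "LabelingCollection",
          function(x) S4Vectors::metadata(x)$droppedObservations)

#' @rdname accessors
#' @export
setMethod("labelLevels", "LabelingCollection",
          function(x) S4Vectors::metadata(x)$labelLevels)

#' @rdname accessors
#' @export
setMethod("sampleId", "LabelingCollection",
          function(x) S4Vectors::metadata(x)$sampleId)

setMethod("show", "LabelingCollection", function(object) {
  cat(sprintf("LabelingCollection: %d observations x %d base clusterings\n",
              nrow(object), ncol(object)))
  nd <- length(S4Vectors::metadata(object)$droppedObservations)
  if (nd) cat(sprintf("  dropped observations: %d\n", nd))
  ks <- vapply(seq_len(ncol(object)),
               function(j) length(unique(SummarizedExperiment::assay(object)[, j])),
               integer(1))
  cat(sprintf("  cluster counts: %s\n", paste(ks, collapse = ", ")))
})

#' Extract one column of a collection as a SpatialLabeling
#'
#' @param collection a \linkS4class{LabelingCollection}.
#' @param column column index or name.
#' @return A \linkS4class{SpatialLabeling}.
#' @export
collectionLabeling <- function(collection, column) {
  if (is.character(column)) column <- match(column, colnames(collection))
  lev <- S4Vectors::metadata(collection)$labelLevels[[column]]
  cd <- SummarizedExperiment::colData(collection)
  codes <- labelMatrix(collection)[, column]
  new("SpatialLabeling",
      obsIds = rownames(collection),
      coords = spatialCoords(collection),
      labels = as.integer(codes),
      labelLevels = lev,
      methodId = cd$methodId[column], configId = cd$configId[column],
      sampleId = as.character(S4Vectors::metadata(collection)$sampleId))
}

#' @rdname accessors
#' @export
setMethod("obsIds", "EntropyField", function(x) x@obsIds)

#' @rdname accessors
#' @export
setMethod("entropyValues", "EntropyField", function(x) {
  v <- x@values
  names(v) <- x@obsIds
  v
})

setMethod("show", "EntropyField", function(object) {
  cat(sprintf("EntropyField: %d observations, mean %.4f nats (bound %.4f)\n",
              length(object@values), mean(object@values),
              object@alphabetBound))
})

#' Mean of an entropy field
#'
#' The scalar summary of a per-observation entropy field: for a
#' smoothness field this is the smoothness entropy (SE) of the labeling;
#' for a cross-method field it is the mean CME.
#'
#' @param x an \linkS4class{EntropyField}.
#' @return A single non-negative number (nats).
#' @export
meanEntropy <- function(x) {
  stopifnot(is(x, "EntropyField"))
  mean(x@values)
}

#' @rdname accessors
#' @export
setMethod("agreementValues", "AgreementMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("provenance", "AgreementMatrix", function(x) x@provenance)

setMethod("show", "AgreementMatrix", function(object) {
  cat(sprintf("AgreementMatrix (%s): %d x %d, off-diagonal range [%.3f, %.3f]\n",
              object@metric, nrow(object@values), ncol(object@values),
              min(object@values[upper.tri(object@values)]),
              max(object@values[upper.tri(object@values)])))
})

#' @rdname accessors
#' @export
setMethod("consensusLabels", "ConsensusResult", function(x) {
  v <- x@labels
  names(v) <- x@obsIds
  v
})

#' @rdname accessors
#' @export
setMethod("consensusWeights", "ConsensusResult", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "ConsensusResult", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("obsIds", "ConsensusResult", function(x) x@obsIds)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult (%s): %d observations, %d clusters%s\n",
              object@algorithm, length(object@labels),
              length(unique(object@labels)),
              if (object@converged) "" else " [not converged]"))
  if (length(object@weights))
    cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
        "\n")
})

#' @rdname accessors
#' @export
setMethod("keptColumns", "SelectionReport", function(x) x@kept)

#' @rdname accessors
#' @export
setMethod("removedColumns", "SelectionReport", function(x) x@removed)

#' @rdname accessors
#' @export
setMethod("blockAssignments", "SelectionReport", function(x) x@blockAssignments)

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: kept %d, removed %d\n",
              nrow(object@kept), nrow(object@removed)))
  if (nrow(object@removed)) {
    tb <- table(object@removed$reason)
    cat("  removal reasons:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("obsIds", "NeighborGraph", function(x) x@obsIds)

#' @rdname accessors
#' @export
setMethod("neighborIndices", "NeighborGraph", function(x) x@neighbors)

#' @rdname accessors
#' @export
setMethod("neighborDistances", "NeighborGraph", function(x) x@distances)

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d observations, k = %d%s\n",
              length(object@obsIds), object@k,
              if (is.finite(object@maxDistance))
                sprintf(", maxDistance = %g", object@maxDistance) else ""))
})

#' @rdname accessors
#' @export
setMethod("meanCme", "SweepGrid", function(x) {
  m <- x@meanCme
  dimnames(m) <- list(k = x@kValues, n = x@nValues)
  m
})

setMethod("show", "SweepGrid", function(object) {
  cat(sprintf("SweepGrid (%s): %d k-values x %d n-values\n",
              object@algorithm, length(object@kValues),
              length(object@nValues)))
  print(meanCme(object))
})

#' @rdname accessors
#' @export
setMethod("obsIds", "SyntheticTissue", function(x) rownames(x@coords))

#' @rdname accessors
#' @export
setMethod("spatialCoords", "SyntheticTissue", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticTissue", function(x) {
  SpatialLabeling(rownames(x@coords), x@coords, x@gtLabels,
                  methodId = "ground-truth", configId = x@layout)
})

setMethod("show", "SyntheticTissue", function(object) {
  cat(sprintf("SyntheticTissue: %d x %d lattice (%s), %d domains, seed %d\n",
              object@nRows, object@nCols, object@layout, object@nDomains,
              object@seed))
})
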