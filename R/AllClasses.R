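#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SpatialLabeling: one clustering result over spatial observations
#'
#' Holds the categorical labels assigned by a single clustering method
#' (one configuration, one sample) together with the 2-D coordinates of
#' the observations (spots, bins or cells). Label values are stored as
#' dense integer codes \code{1..K}; the original label strings are kept
#' in \code{labelLevels}.
#'
#' @slot obsIds character, unique observation identifiers.
#' @slot coords numeric matrix with columns \code{x}, \code{y}, one row
#'   per observation.
#' @slot labels integer codes in \code{1..K}, one per observation.
#' @slot labelLevels character of length K; original label strings,
#'   position i is the string for code i.
#' @slot methodId,configId,sampleId provenance strings (sampleId may be
#'   \code{NA}).
#'
#' @exportClass SpatialLabeling
setClass("SpatialLabeling",
  representation(
    obsIds      = "character",
    coords      = "matrix",
    labels      = "integer",
    labelLevels = "character",
    methodId    = "character",
    configId    = "character",
    sampleId    = "character"
  )
)

setValidity("SpatialLabeling", function(object) {
  msg <- character()
  n <- length(object@obsIds)
  if (anyDuplicated(object@obsIds))
    msg <- c(msg, sprintf("duplicated observation id: '%s'",
                          object@obsIds[duplicated(object@obsIds)][1L]))
  if (nrow(object@coords) != n || length(object@labels) != n)
    msg <- c(msg, "obsIds, coords and labels must have equal length")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y)")
  if (n > 0 && !all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  K <- length(object@labelLevels)
  if (K < 1L)
    msg <- c(msg, "label alphabet must have size >= 1")
  if (n > 0) {
    if (anyNA(object@labels))
      msg <- c(msg, "labels must not contain NA")
    else if (!setequal(sort(unique(object@labels)), seq_len(K)))
      msg <- c(msg, "labels must be a dense recoding 1..K matching labelLevels")
  }
  if (length(object@methodId) != 1L || length(object@configId) != 1L)
    msg <- c(msg, "methodId and configId must be single strings")
  if (length(msg)) msg else TRUE
})

#' LabelingCollection: several base clusterings on a shared index
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"labels"} assay
#' is an N (observations) x M (base clusterings) integer matrix of dense
#' per-column codes, \code{rowData} carries the shared \code{x}, \code{y}
#' coordinates, \code{colData} carries per-column provenance
#' (\code{methodId}, \code{configId}). \code{metadata()} stores
#' \code{droppedObservations} (ids removed when intersecting the inputs),
#' \code{labelLevels} (per-column code-to-string maps) and
#' \code{sampleId}.
#'
#' @exportClass LabelingCollection
setClass("LabelingCollection", contains = "SummarizedExperiment")

setValidity("LabelingCollection", function(object) {
  msg <- character()
  if (!"labels" %in% SummarizedExperiment::assayNames(object))
    return("assay 'labels' is required")
  L <- SummarizedExperiment::assay(object, "labels")
  if (!is.integer(L))
    msg <- c(msg, "assay 'labels' must be an integer matrix")
  if (anyNA(L))
    msg <- c(msg, "label matrix must not contain NA (intersection semantics)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "observation ids (rownames) must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("x", "y") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain coordinates 'x' and 'y'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("methodId", "configId") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'methodId' and 'configId'")
  if (is.integer(L) && !anyNA(L) && nrow(L) > 0) {
    for (j in seq_len(ncol(L))) {
      u <- sort(unique(L[, j]))
      if (!identical(u, seq_along(u)))
        msg <- c(msg, sprintf("column %d is not a dense 1..K recoding", j))
    }
  }
  if (length(msg)) msg else TRUE
})

#' NeighborGraph: k-nearest spatial neighbors per observation
#'
#' Per-observation neighbor lists (indices into the observation order),
#' sorted by ascending distance; an observation is never its own
#' neighbor. When built with a distance cutoff, neighbors beyond
#' \code{maxDistance} are removed after the k-selection, so lists may be
#' shorter than k (possibly empty).
#'
#' @slot obsIds character observation ids (defines the index order).
#' @slot k integer, the number of neighbors requested.
#' @slot neighbors list of integer vectors (indices), ascending distance.
#' @slot distances list of numeric vectors matching \code{neighbors}.
#' @slot maxDistance numeric cutoff, \code{Inf} when unused.
#'
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  representation(
    obsIds      = "character",
    k           = "integer",
    neighbors   = "list",
    distances   = "list",
    maxDistance = "numeric"
  )
)

setValidity("NeighborGraph", function(object) {
  msg <- character()
  n <- length(object@obsIds)
  if (length(object@neighbors) != n || length(object@distances) != n)
    msg <- c(msg, "neighbor and distance lists must match obsIds length")
  for (i in seq_len(n)) {
    nb <- object@neighbors[[i]]
    d <- object@distances[[i]]
    if (length(nb) != length(d)) {
      msg <- c(msg, sprintf("observation %d: neighbors/distances mismatch", i))
      break
    }
    if (any(nb == i)) {
      msg <- c(msg, sprintf("observation %d is its own neighbor", i))
      break
    }
    if (is.unsorted(d)) {
      msg <- c(msg, sprintf("observation %d: distances not ascending", i))
      break
    }
    if (length(d) && d[length(d)] > object@maxDistance) {
      msg <- c(msg, sprintf("observation %d: distance beyond maxDistance", i))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' EntropyField: per-observation non-negative entropy values
#'
#' Used both for smoothness-entropy contributions (entropy of the labels
#' in each observation's spatial neighborhood) and for cross-method
#' entropy maps (entropy of aligned labels across methods). Values are
#' in nats and bounded by \code{log} of the relevant alphabet size.
#'
#' @slot obsIds character observation ids.
#' @slot values numeric, one non-negative entropy per observation.
#' @slot alphabetBound numeric upper bound \code{log(max class count)}.
#'
#' @exportClass EntropyField
setClass("EntropyField",
  representation(
    obsIds        = "character",
    values        = "numeric",
    alphabetBound = "numeric"
  )
)

setValidity("EntropyField", function(object) {
  msg <- character()
  if (length(object@values) != length(object@obsIds))
    msg <- c(msg, "values and obsIds must have equal length")
  if (length(object@values) &&
      (min(object@values) < -1e-12 ||
       max(object@values) > object@alphabetBound + 1e-9))
    msg <- c(msg, "entropy values must lie in [0, alphabetBound]")
  if (length(msg)) msg else TRUE
})

#' AgreementMatrix: pairwise partition agreement between base clusterings
#'
#' Symmetric M x M matrix of ARI or NMI scores with unit diagonal;
#' row/column names carry the column provenance of the collection.
#'
#' @slot values symmetric numeric matrix, diagonal 1.
#' @slot metric one of \code{"ARI"}, \code{"NMI"}.
#' @slot provenance data.frame with \code{methodId}, \code{configId}.
#'
#' @exportClass AgreementMatrix
setClass("AgreementMatrix",
  representation(
    values     = "matrix",
    metric     = "character",
    provenance = "data.frame"
  )
)

setValidity("AgreementMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v))
    msg <- c(msg, "agreement matrix must be square")
  else {
    if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "agreement matrix must be symmetric within 1e-12")
    if (any(abs(diag(v) - 1) > 1e-12))
      msg <- c(msg, "diagonal must be 1 (self-agreement)")
  }
  if (!object@metric %in% c("ARI", "NMI"))
    msg <- c(msg, "metric must be 'ARI' or 'NMI'")
  if (object@metric == "ARI" && nrow(v) && max(v) > 1 + 1e-12)
    msg <- c(msg, "ARI entries must be <= 1")
  if (length(msg)) msg else TRUE
})

#' SelectionReport: audit record of a base-clustering selection step
#'
#' @slot kept data.frame of surviving columns (\code{column},
#'   \code{methodId}, \code{configId}).
#' @slot removed data.frame with the same columns plus \code{reason},
#'   one of \code{imbalance}, \code{duplicate-algorithm},
#'   \code{out-of-block}, \code{rank-cutoff}.
#' @slot blockAssignments integer block id per column (concordance step
#'   only; length 0 otherwise), named by column.
#' @slot nGroups integer number of tree-cut groups used (NA otherwise).
#'
#' @exportClass SelectionReport
setClass("SelectionReport",
  representation(
    kept             = "data.frame",
    removed          = "data.frame",
    blockAssignments = "integer",
    nGroups          = "integer"
  )
)

setValidity("SelectionReport", function(object) {
  msg <- character()
  ok <- c("imbalance", "duplicate-algorithm", "out-of-block", "rank-cutoff")
  if (nrow(object@removed) && !all(object@removed$reason %in% ok))
    msg <- c(msg, "invalid removal reason")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: the output of a consensus algorithm
#'
#' @slot labels integer consensus codes per observation.
#' @slot obsIds character observation ids.
#' @slot K integer, the requested number of consensus clusters
#'   (NA when the weighted algorithm chose the count itself).
#' @slot algorithm one of \code{"kmodes"}, \code{"lca"}, \code{"weighted"}.
#' @slot seed integer seed used.
#' @slot objectiveTrace numeric per-iteration objective of the winning
#'   run: Hamming objective (kmodes, non-increasing), penalized
#'   log-likelihood (lca, non-decreasing), regularized JSD objective
#'   (weighted, non-increasing).
#' @slot weights per-column weights (weighted algorithm only; length 0
#'   otherwise), non-negative, summing to 1.
#' @slot converged logical.
#'
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(
    labels         = "integer",
    obsIds         = "character",
    K              = "integer",
    algorithm      = "character",
    seed           = "integer",
    objectiveTrace = "numeric",
    weights        = "numeric",
    converged      = "logical"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@obsIds))
    msg <- c(msg, "labels and obsIds must have equal length")
  if (!object@algorithm %in% c("kmodes", "lca", "weighted"))
    msg <- c(msg, "algorithm must be kmodes, lca or weighted")
  if (!is.na(object@K) && length(unique(object@labels)) > object@K)
    msg <- c(msg, "labels use more than K distinct codes")
  if (length(object@weights)) {
    if (any(object@weights < -1e-12))
      msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 within 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' LcaModel: fitted latent class model behind an LCA consensus
#'
#' @slot classPriors numeric K, non-negative, summing to 1.
#' @slot conditionals list over base clusterings; element m is a
#'   K x K_m matrix of P(observed label j | latent class k), rows
#'   summing to 1.
#' @slot logLik numeric observed-data log-likelihood at the optimum.
#'
#' @exportClass LcaModel
setClass("LcaModel",
  representation(
    classPriors  = "numeric",
    conditionals = "list",
    logLik       = "numeric"
  )
)

setValidity("LcaModel", function(object) {
  msg <- character()
  if (abs(sum(object@classPriors) - 1) > 1e-9 || any(object@classPriors < 0))
    msg <- c(msg, "classPriors must be non-negative and sum to 1")
  for (m in seq_along(object@conditionals)) {
    th <- object@conditionals[[m]]
    if (any(abs(rowSums(th) - 1) > 1e-9))
      msg <- c(msg, sprintf("conditionals[[%d]] rows must sum to 1", m))
  }
  if (length(msg)) msg else TRUE
})

#' SweepGrid: mean cross-method entropy over (clusters x methods) cells
#'
#' @slot kValues integer numbers of clusters (grid rows).
#' @slot nValues integer numbers of smoothest base clusterings (columns).
#' @slot meanCme numeric matrix of mean CME per cell (NA when infeasible).
#' @slot feasible logical matrix; FALSE when a cell had fewer than n
#'   columns available.
#' @slot degenerate logical matrix; TRUE for n = 1 cells (a single
#'   labeling has no cross-method disagreement; the 0 is definitional).
#' @slot algorithm,seed provenance of any consensus computed per cell.
#'
#' @exportClass SweepGrid
setClass("SweepGrid",
  representation(
    kValues    = "integer",
    nValues    = "integer",
    meanCme    = "matrix",
    feasible   = "matrix",
    degenerate = "matrix",
    algorithm  = "character",
    seed       = "integer"
  )
)

setValidity("SweepGrid", function(object) {
  d <- c(length(object@kValues), length(object@nValues))
  if (!identical(dim(object@meanCme), d) ||
      !identical(dim(object@feasible), d) ||
      !identical(dim(object@degenerate), d))
    return("grid matrices must be |kValues| x |nValues|")
  v <- object@meanCme[object@feasible]
  if (length(v) && any(v < -1e-12, na.rm = TRUE))
    return("mean CME must be non-negative")
  TRUE
})

#' SyntheticTissue: lattice tissue with known spatial domains
#'
#' Observations sit on a square grid with unit spacing; ground-truth
#' domains are spatially connected sets (horizontal bands for the
#' \code{"layers"} layout, rectangles for \code{"blocks"}).
#'
#' @slot coords numeric matrix (x, y), rownames are observation ids.
#' @slot gtLabels integer domain codes 1..nDomains.
#' @slot layout \code{"layers"} or \code{"blocks"}.
#' @slot nDomains,nRows,nCols,seed integers.
#'
#' @exportClass SyntheticTissue
setClass("SyntheticTissue",
  representation(
    coords   = "matrix",
    gtLabels = "integer",
    layout   = "character",
    nDomains = "integer",
    nRows    = "integer",
    nCols    = "integer",
    seed     = "integer"
  )
)

setValidity("SyntheticTissue", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@gtLabels))
    msg <- c(msg, "coords and gtLabels must have equal length")
  if (!object@layout %in% c("layers", "blocks"))
    msg <- c(msg, "layout must be 'layers' or 'blocks'")
  if (length(unique(object@gtLabels)) != object@nDomains)
    msg <- c(msg, "all domains must be non-empty")
  if (length(msg)) msg else TRUE
})

#' NoiseSpec: perturbation recipe for a synthetic base clustering
#'
#' Perturbations are applied in a fixed order: merges, splits, boundary
#' jitter, independent label flips, optional label permutation.
#'
#' @slot flipRate per-observation probability in [0, 1) of reassignment
#'   to a uniformly random other label.
#' @slot jitterRadius lattice-step radius around domain boundaries
#'   within which observations are eligible for jitter (0 disables).
#' @slot jitterProb probability that an eligible observation is
#'   reassigned to the nearest adjacent domain.
#' @slot splits integer domain ids to split at their coordinate median.
#' @slot merges list of integer pairs of domain ids to merge.
#' @slot permuteLabels logical; randomly permute the label codes.
#' @slot seed integer.
#'
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(
    flipRate      = "numeric",
    jitterRadius  = "numeric",
    jitterProb    = "numeric",
    splits        = "integer",
    merges        = "list",
    permuteLabels = "logical",
    seed          = "integer"
  )
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (object@flipRate < 0 || object@flipRate >= 1)
    msg <- c(msg, "flipRate must lie in [0, 1)")
  if (object@jitterProb < 0 || object@jitterProb > 1)
    msg <- c(msg, "jitterProb must lie in [0, 1]")
  if (object@jitterRadius < 0)
    msg <- c(msg, "jitterRadius must be >= 0")
  for (p in object@merges)
    if (length(p) != 2L) msg <- c(msg, "each merge must be a pair of domains")
  if (length(msg)) msg else TRUE
})
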