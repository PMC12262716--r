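#' Run one of the three consensus algorithms by name
#'
#' Thin dispatcher used by the leave-one-out and sweep routines and by
#' the command-line interface.
#'
#' @inheritParams kmodesConsensus
#' @param algorithm \code{"kmodes"}, \code{"lca"} or \code{"weighted"}.
#' @param ... passed to the chosen algorithm.
#' @return A \linkS4class{ConsensusResult}.
#' @export
runConsensus <- function(collection, algorithm = c("lca", "kmodes", "weighted"),
                         K, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         kmodes = kmodesConsensus(collection, K = K, seed = seed, ...),
         lca = lcaConsensus(collection, K = K, seed = seed, ...)$result,
         weighted = weightedConsensus(collection, K = K, seed = seed, ...))
}

#' Leave-one-out pseudo-ground-truth validation
#'
#' For every base clustering c, a consensus is built from the
#' \code{nBase} smoothest of the remaining columns (per-algorithm
#' deduplication applied) and the ARI between c and that consensus is
#' reported. A column scoring low against the consensus of its peers is
#' an outlier among the base clusterings; the scores rank methods
#' without relying on a possibly biased external ground truth.
#'
#' @param collection a \linkS4class{LabelingCollection} of the selected
#'   base clusterings.
#' @param seValues named numeric smoothness entropy per column.
#' @param K number of consensus clusters.
#' @param algorithm consensus algorithm (default \code{"lca"}).
#' @param nBase number of peers per consensus (default 6).
#' @param seed integer.
#' @param ... passed to the consensus algorithm.
#' @return Named numeric vector of leave-one-out ARIs, one per column.
#' @export
leaveOneOut <- function(collection, seValues, K,
                        algorithm = c("lca", "kmodes", "weighted"),
                        nBase = 6L, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  M <- ncol(collection)
  if (M < nBase + 1L)
    stop(sprintf("leave-one-out needs at least nBase + 1 = %d columns (have %d)",
                 nBase + 1L, M))
  L <- labelMatrix(collection)
  out <- numeric(M)
  for (cidx in seq_len(M)) {
    rest <- subsetColumns(collection, setdiff(seq_len(M), cidx))
    sel <- suppressWarnings(
      selectSmoothest(rest, seValues[-cidx], n = nBase, dedupe = TRUE))
    cons <- runConsensus(sel$collection, algorithm = algorithm, K = K,
                         seed = seed, ...)
    out[cidx] <- ariScore(L[, cidx], cons@labels)
  }
  names(out) <- colnames(collection)
  out
}

#' Mean-CME grid over cluster count and number of methods
#'
#' For every pair (k, n) with k a cluster count and n a number of base
#' clusterings, selects the n smoothest (per-algorithm deduplicated)
#' columns of the k-cluster collection and stores the mean cross-method
#' entropy over observations. Low mean CME marks granularities at which
#' methods agree; the grid mirrors the usual sweep used to pick a
#' cluster number when no trustworthy ground truth exists. Cells with
#' fewer than n available columns are marked infeasible; n = 1 cells are
#' 0 by definition (one labeling cannot disagree with itself) and are
#' flagged degenerate.
#'
#' @param collectionsByK named list (names = k) of
#'   \linkS4class{LabelingCollection}s whose columns all have exactly k
#'   classes (e.g. from [granularityCollections()]).
#' @param seValuesByK list of per-column SE vectors matching
#'   \code{collectionsByK}; computed with [smoothnessScores()] when NULL.
#' @param nValues integer numbers of methods to sweep.
#' @param algorithm recorded provenance tag (default \code{"lca"}).
#' @param seed integer recorded provenance.
#' @return A \linkS4class{SweepGrid}.
#' @export
sweepGrid <- function(collectionsByK, seValuesByK = NULL, nValues,
                      algorithm = "lca", seed = 1L) {
  kValues <- as.integer(names(collectionsByK))
  if (anyNA(kValues)) stop("collectionsByK must be named by cluster count")
  nValues <- as.integer(nValues)
  if (is.null(seValuesByK))
    seValuesByK <- lapply(collectionsByK, smoothnessScores)

  dims <- c(length(kValues), length(nValues))
  cme <- matrix(NA_real_, dims[1], dims[2])
  feasible <- matrix(FALSE, dims[1], dims[2])
  degenerate <- matrix(FALSE, dims[1], dims[2])
  for (ki in seq_along(kValues)) {
    coll <- collectionsByK[[ki]]
    se <- seValuesByK[[ki]]
    for (ni in seq_along(nValues)) {
      n <- nValues[ni]
      if (ncol(coll) < n) next  # infeasible cell
      sel <- suppressWarnings(selectSmoothest(coll, se, n = n, dedupe = TRUE))
      if (ncol(sel$collection) < n) next  # dedupe left fewer than n
      feasible[ki, ni] <- TRUE
      if (n == 1L) {
        cme[ki, ni] <- 0
        degenerate[ki, ni] <- TRUE
      } else {
        cme[ki, ni] <- meanEntropy(crossMethodEntropy(sel$collection))
      }
    }
  }
  new("SweepGrid", kValues = kValues, nValues = nValues,
      meanCme = cme, feasible = feasible, degenerate = degenerate,
      algorithm = algorithm, seed = as.integer(seed))
}
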