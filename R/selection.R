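emptyProv <- function() {
  data.frame(column = character(), methodId = character(),
             configId = character(), stringsAsFactors = FALSE)
}

provRows <- function(collection, idx, reason = NULL) {
  p <- provenance(collection)[idx, , drop = FALSE]
  rownames(p) <- NULL
  if (!is.null(reason) && nrow(p)) p$reason <- reason
  if (!is.null(reason) && !nrow(p)) p$reason <- character()
  p
}

#' Drop base clusterings dominated by one class
#'
#' Removes every column whose modal class frequency strictly exceeds
#' \code{threshold} (default 0.9: a clustering in which one cluster
#' holds more than 90\% of the observations carries little structure and
#' distorts consensus).
#'
#' @param collection a \linkS4class{LabelingCollection}.
#' @param threshold fraction in (0, 1].
#' @return A list with the filtered \code{collection} and a
#'   \linkS4class{SelectionReport}.
#' @export
filterImbalanced <- function(collection, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  L <- labelMatrix(collection)
  modal <- vapply(seq_len(ncol(L)),
                  function(j) max(tabulate(L[, j])) / nrow(L), numeric(1))
  drop <- modal > threshold
  if (all(drop))
    stop(sprintf(
      "all %d base clusterings exceed the %.0f%% imbalance threshold; try a higher threshold",
      ncol(L), 100 * threshold))
  report <- new("SelectionReport",
                kept = provRows(collection, which(!drop)),
                removed = provRows(collection, which(drop), "imbalance"),
                blockAssignments = integer(), nGroups = NA_integer_)
  list(collection = subsetColumns(collection, which(!drop)), report = report)
}

## deterministic provenance order: methodId, then configId, then column name
provOrder <- function(prov) {
  order(prov$methodId, prov$configId, prov$column, method = "radix")
}

#' Keep the n spatially smoothest base clusterings
#'
#' Ranks columns by smoothness entropy (ascending; lower = smoother).
#' With \code{dedupe = TRUE}, only the smoothest column per method
#' survives first (algorithm diversity), then the n lowest-SE survivors
#' are kept. Ties are broken by lexicographic provenance order.
#'
#' @param collection a \linkS4class{LabelingCollection}.
#' @param seValues named numeric, one SE value per column (e.g. from
#'   [smoothnessScores()]).
#' @param n number of columns to keep.
#' @param dedupe keep at most one column per \code{methodId} first.
#' @return A list with the selected \code{collection} and a
#'   \linkS4class{SelectionReport}.
#' @export
selectSmoothest <- function(collection, seValues, n, dedupe = TRUE) {
  stopifnot(n >= 1L, length(seValues) == ncol(collection))
  prov <- provenance(collection)
  ord <- order(seValues, provOrder(prov), method = "radix")

  removed <- emptyProv(); removed$reason <- character()
  keepIdx <- ord
  if (dedupe) {
    firstOfMethod <- !duplicated(prov$methodId[ord])
    dup <- ord[!firstOfMethod]
    removed <- rbind(removed, provRows(collection, dup, "duplicate-algorithm"))
    keepIdx <- ord[firstOfMethod]
  }
  if (n > length(keepIdx)) {
    warning(sprintf("requested n = %d but only %d column(s) survive; keeping all",
                    n, length(keepIdx)))
  } else if (n < length(keepIdx)) {
    cut <- keepIdx[-seq_len(n)]
    removed <- rbind(removed, provRows(collection, cut, "rank-cutoff"))
    keepIdx <- keepIdx[seq_len(n)]
  }
  keepIdx <- sort(keepIdx)  # preserve original column order
  report <- new("SelectionReport",
                kept = provRows(collection, keepIdx),
                removed = removed,
                blockAssignments = integer(), nGroups = NA_integer_)
  list(collection = subsetColumns(collection, keepIdx), report = report)
}

#' Concordance block on an agreement matrix
#'
#' Rows of the pairwise ARI/NMI matrix are hierarchically clustered
#' (Euclidean row distance, complete linkage) and the tree is cut into
#' \code{nGroups}. The selected block is the group with the highest mean
#' within-group agreement among groups of size at least
#' \code{minBlockSize} (a consensus of fewer than 3 members is
#' degenerate, hence the default).
#'
#' @param agreement an \linkS4class{AgreementMatrix}.
#' @param nGroups number of groups to cut the tree into (default 2).
#' @param minBlockSize minimum size of an eligible block (default 3).
#' @return A \linkS4class{SelectionReport}; \code{blockAssignments}
#'   holds the group id of every column, \code{kept} the winning block.
#' @export
concordanceBlock <- function(agreement, nGroups = 2L, minBlockSize = 3L) {
  stopifnot(is(agreement, "AgreementMatrix"))
  v <- agreement@values
  M <- nrow(v)
  if (M < nGroups) stop("need at least nGroups base clusterings")
  hc <- stats::hclust(stats::dist(v, method = "euclidean"),
                      method = "complete")
  grp <- stats::cutree(hc, k = nGroups)
  sizes <- table(grp)
  eligible <- as.integer(names(sizes)[sizes >= minBlockSize])
  if (!length(eligible))
    stop(sprintf("no group reaches minBlockSize = %d (group sizes: %s)",
                 minBlockSize, paste(sizes, collapse = ", ")))
  meanInternal <- vapply(eligible, function(g) {
    idx <- which(grp == g)
    if (length(idx) == 1L) return(1)
    w <- v[idx, idx]
    mean(w[upper.tri(w)])
  }, numeric(1))
  best <- eligible[order(-meanInternal, eligible)][1L]
  keep <- which(grp == best)

  prov <- agreement@provenance
  prov$column <- rownames(v)
  prov <- prov[, c("column", "methodId", "configId")]
  kept <- prov[keep, , drop = FALSE]; rownames(kept) <- NULL
  removed <- prov[-keep, , drop = FALSE]; rownames(removed) <- NULL
  if (nrow(removed)) removed$reason <- "out-of-block"
  else removed$reason <- character()
  ba <- as.integer(grp); names(ba) <- rownames(v)
  new("SelectionReport", kept = kept, removed = removed,
      blockAssignments = ba, nGroups = as.integer(nGroups))
}
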