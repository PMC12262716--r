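#' Shannon entropy of a categorical vector
#'
#' \eqn{H(X) = -\sum_i p_i \log p_i} with \eqn{p_i} the empirical class
#' frequencies, natural logarithm (nats), and \eqn{0 \log 0 \equiv 0}.
#'
#' @param labels non-empty vector of categorical values (character,
#'   factor or integer).
#' @return A single non-negative number; 0 for a single-class vector,
#'   at most \code{log(m)} for m classes.
#' @examples
#' shannonEntropy(c("a", "b"))        # log(2)
#' shannonEntropy(c("a", "a", "b", "c"))
#' @export
shannonEntropy <- function(labels) {
  if (length(labels) == 0L)
    stop("cannot compute entropy of an empty vector")
  p <- tabulate(as.integer(factor(labels)))
  p <- p / sum(p)
  -sum(p * log(p))
}

## entropy of integer codes 1..max, skipping the factor() pass (hot path)
entropyCodes <- function(codes, nmax) {
  p <- tabulate(codes, nbins = nmax)
  p <- p[p > 0L] / length(codes)
  -sum(p * log(p))
}

#' Build a k-nearest-neighbor graph on spatial coordinates
#'
#' Exact Euclidean k-NN. Ties at equal distance are broken by ascending
#' observation-id order, so the graph is deterministic. When
#' \code{maxDistance} is given, neighbors beyond the cutoff are removed
#' after the k-selection (lists may then hold fewer than k entries).
#'
#' @param coords numeric matrix (x, y) with rownames as observation ids,
#'   or a \linkS4class{SpatialLabeling}/\linkS4class{LabelingCollection}.
#' @param k number of neighbors, \code{1 <= k <= N - 1}.
#' @param maxDistance optional distance cutoff (e.g. 1.5 on a unit
#'   lattice keeps rook and diagonal neighbors only).
#'
#' @return A \linkS4class{NeighborGraph}.
#' @export
buildKnnGraph <- function(coords, k, maxDistance = NULL) {
  if (is(coords, "SpatialLabeling") || is(coords, "LabelingCollection"))
    coords <- spatialCoords(coords)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 observations")
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop(sprintf("k must satisfy 1 <= k <= N - 1 (k = %d, N = %d)", k, n))
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  idRank <- match(ids, stringSort(ids))  # tie-break key
  cutoff <- if (is.null(maxDistance)) Inf else as.numeric(maxDistance)

  xs <- coords[, 1L]; ys <- coords[, 2L]
  neighbors <- vector("list", n)
  distances <- vector("list", n)
  chunk <- max(1L, min(n, as.integer(2e7 / n)))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    d2 <- outer(xs[rows], xs, "-")^2 + outer(ys[rows], ys, "-")^2
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      d <- sqrt(d2[ii, ])
      d[i] <- Inf
      ord <- order(d, idRank)[seq_len(k)]
      keep <- d[ord] <= cutoff
      neighbors[[i]] <- ord[keep]
      distances[[i]] <- d[ord][keep]
    }
  }
  new("NeighborGraph", obsIds = ids, k = k,
      neighbors = neighbors, distances = distances, maxDistance = cutoff)
}

checkGraphMatch <- function(labeling, graph) {
  if (!identical(obsIds(labeling), graph@obsIds))
    stop("graph and labeling observation ids do not match")
}

#' Smoothness entropy field of a labeling
#'
#' For every observation, the Shannon entropy of the label multiset
#' formed by the observation itself and its retained spatial neighbors;
#' low values mean spatially coherent (smooth) domains. The scalar
#' smoothness entropy (SE) of the labeling is the mean of this field
#' (see [meanEntropy()]). Observations whose neighbor list is empty
#' after distance filtering contribute entropy 0.
#'
#' @param labeling a \linkS4class{SpatialLabeling}.
#' @param graph a \linkS4class{NeighborGraph} built on the labeling's
#'   coordinates; built on the fly with \code{k} neighbors when omitted.
#' @param k neighbors used when \code{graph} is missing (default 6).
#'
#' @return An \linkS4class{EntropyField}.
#' @export
smoothnessEntropy <- function(labeling, graph = NULL, k = 6) {
  stopifnot(is(labeling, "SpatialLabeling"))
  if (is.null(graph))
    graph <- buildKnnGraph(spatialCoords(labeling), k = k)
  checkGraphMatch(labeling, graph)
  lab <- labeling@labels
  K <- length(labeling@labelLevels)
  vals <- vapply(seq_along(lab), function(i) {
    entropyCodes(c(lab[i], lab[graph@neighbors[[i]]]), K)
  }, numeric(1))
  new("EntropyField", obsIds = labeling@obsIds, values = vals,
      alphabetBound = log(max(2L, K)))
}

#' Per-column smoothness entropy of a collection
#'
#' @param collection a \linkS4class{LabelingCollection}.
#' @param k neighbors (default 6).
#' @param maxDistance optional cutoff passed to [buildKnnGraph()].
#' @return Named numeric, one SE value per column.
#' @export
smoothnessScores <- function(collection, k = 6, maxDistance = NULL) {
  graph <- buildKnnGraph(spatialCoords(collection), k = k,
                         maxDistance = maxDistance)
  L <- labelMatrix(collection)
  out <- vapply(seq_len(ncol(L)), function(j) {
    lab <- L[, j]
    K <- max(lab)
    mean(vapply(seq_along(lab), function(i) {
      entropyCodes(c(lab[i], lab[graph@neighbors[[i]]]), K)
    }, numeric(1)))
  }, numeric(1))
  names(out) <- colnames(collection)
  out
}

#' Border mask: observations adjacent to a different domain
#'
#' An observation is a border spot iff any retained neighbor carries a
#' different label. An observation with no retained neighbors (all
#' filtered by the distance cutoff) is not a border spot. Defaults
#' follow the usual lattice convention: \code{k = 4} neighbors with a
#' distance cutoff of 1.5 grid units.
#'
#' @inheritParams smoothnessEntropy
#' @param k,maxDistance used when \code{graph} is missing.
#' @return Named logical vector.
#' @export
borderMask <- function(labeling, graph = NULL, k = 4, maxDistance = 1.5) {
  stopifnot(is(labeling, "SpatialLabeling"))
  if (is.null(graph))
    graph <- buildKnnGraph(spatialCoords(labeling), k = k,
                           maxDistance = maxDistance)
  checkGraphMatch(labeling, graph)
  lab <- labeling@labels
  out <- vapply(seq_along(lab), function(i) {
    nb <- graph@neighbors[[i]]
    length(nb) > 0L && any(lab[nb] != lab[i])
  }, logical(1))
  names(out) <- labeling@obsIds
  out
}

#' Adjusted Rand index of two partitions
#'
#' Permutation-model chance-corrected Rand index, computed from the
#' contingency table. In the degenerate case where the expected index
#' equals the maximum index (e.g. both partitions are a single class),
#' the score is 1 if the two vectors induce identical set partitions and
#' 0 otherwise.
#'
#' @param a,b label vectors over the same observations.
#' @return ARI in \eqn{[-1, 1]}.
#' @export
ariScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  ct <- table(a, b)
  n <- length(a)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  expected <- si * sj / choose(n, 2)
  maximum <- (si + sj) / 2
  if (abs(maximum - expected) < .Machine$double.eps * max(1, maximum)) {
    samePartition <- all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L)
    return(if (samePartition) 1 else 0)
  }
  (sij - expected) / (maximum - expected)
}

#' Normalized mutual information of two partitions
#'
#' Mutual information normalized by the arithmetic mean of the marginal
#' entropies, \eqn{2 I(X;Y) / (H(X) + H(Y))} (natural log). When both
#' marginal entropies are zero the score is 1 (two single-class
#' partitions are identical).
#'
#' @inheritParams ariScore
#' @return NMI in \eqn{[0, 1]}.
#' @export
nmiScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  ct <- table(a, b) / length(a)
  px <- rowSums(ct); py <- colSums(ct)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)
  nz <- ct > 0
  mi <- sum(ct[nz] * log(ct[nz] / outer(px, py)[nz]))
  max(0, 2 * mi / (hx + hy))
}

#' Pairwise agreement matrix across base clusterings
#'
#' @param collection a \linkS4class{LabelingCollection} with at least
#'   two columns.
#' @param metric \code{"ARI"} (default) or \code{"NMI"}.
#' @return An \linkS4class{AgreementMatrix}.
#' @export
pairwiseAgreement <- function(collection, metric = c("ARI", "NMI")) {
  metric <- match.arg(metric)
  L <- labelMatrix(collection)
  M <- ncol(L)
  if (M < 2L) stop("need at least two base clusterings")
  fun <- if (metric == "ARI") ariScore else nmiScore
  v <- diag(nrow = M)
  for (i in seq_len(M - 1L))
    for (j in (i + 1L):M)
      v[i, j] <- v[j, i] <- fun(L[, i], L[, j])
  dimnames(v) <- list(colnames(L), colnames(L))
  new("AgreementMatrix", values = v, metric = metric,
      provenance = provenance(collection))
}
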