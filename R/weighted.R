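#' Jensen-Shannon divergence of two Bernoulli distributions
#'
#' \eqn{\mathrm{JSD}(p, q) = \tfrac12 KL(p \| m) + \tfrac12 KL(q \| m)}
#' with \eqn{m = (p + q)/2}, natural log, \eqn{0 \log 0 \equiv 0}.
#' Vectorized over both arguments. Bounded by \eqn{\log 2}, attained at
#' \code{bernoulliJSD(0, 1)}.
#'
#' @param p,q success probabilities in \eqn{[0, 1]} (recycled).
#' @return Non-negative divergence values in nats.
#' @export
bernoulliJSD <- function(p, q) {
  if (any(p < 0 | p > 1 | q < 0 | q > 1))
    stop("p and q must lie in [0, 1]")
  m <- (p + q) / 2
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  kl <- function(a, b) xlogx(a) - ifelse(a > 0, a * log(b), 0) +
    xlogx(1 - a) - ifelse(a < 1, (1 - a) * log(1 - b), 0)
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Binary co-association matrix of one labeling
#'
#' \eqn{s_{ij} = 1} iff observations i and j share a label. Unit
#' diagonal.
#'
#' @param labels label vector.
#' @return An N x N 0/1 numeric matrix.
#' @export
coassociationMatrix <- function(labels) {
  outer(labels, labels, "==") * 1
}

## upper-triangle (i < j) vector of a square matrix
upperVec <- function(m) m[upper.tri(m)]

## minimize f(s) = (1 - w) jsd(s, 0) + w jsd(s, 1) over s in [0, 1];
## convex in s, solved by bounded scalar minimization
solveEntry <- function(w) {
  if (w <= 0) return(0)
  if (w >= 1) return(1)
  stats::optimize(function(s) (1 - w) * bernoulliJSD(s, 0) + w * bernoulliJSD(s, 1),
                  interval = c(0, 1), tol = 1e-12)$minimum
}

#' Weighted Jensen-Shannon co-association consensus
#'
#' Finds a consensus co-association matrix S and per-method weights
#' \eqn{\omega_m} minimizing
#' \deqn{\sum_m \omega_m \mathrm{JSD}(S \| S^{(m)}) +
#'       \lambda \sum_m \omega_m \log \omega_m, \quad
#'       \sum_m \omega_m = 1,\ \omega_m \ge 0,}
#' where \eqn{S^{(m)}} is the binary co-association matrix of base
#' clustering m and the divergence is summed entrywise over distinct
#' pairs (diagonal self-pairs carry no information and are excluded).
#' The entropy term keeps the weights from collapsing onto a single
#' base clustering.
#'
#' Optimization alternates two exact sub-problem solutions: with
#' \eqn{\omega} fixed, each entry \eqn{s_{ij}} solves a 1-D convex
#' problem that depends only on the weighted vote
#' \eqn{w_{ij} = \sum_m \omega_m s^{(m)}_{ij}}; with S fixed, the
#' Lagrangian stationarity condition gives the closed form
#' \eqn{\omega_m \propto \exp(-\mathrm{JSD}(S \| S^{(m)}) / \lambda)}.
#' The objective is therefore non-increasing. The converged S is
#' partitioned with the Leiden algorithm (modularity, igraph) on the
#' graph whose edge weights are the entries of S above
#' \code{sparsify}; when \code{K} is given the Leiden resolution is
#' driven to K clusters via [resolutionSearch()].
#'
#' Dense N x N storage bounds the problem size; inputs above
#' \code{maxN} observations are rejected.
#'
#' @inheritParams kmodesConsensus
#' @param lambda entropy-regularization strength (> 0, default 0.1).
#'   Large values force near-uniform weights.
#' @param K optional target number of consensus clusters.
#' @param tol convergence threshold on the objective change (default 1e-8).
#' @param maxIter alternating-update cap (default 100).
#' @param sparsify drop S entries below this value when building the
#'   Leiden graph (default 0.01).
#' @param maxN hard cap on N for dense storage (default 20000).
#' @return A \linkS4class{ConsensusResult} with per-method
#'   \code{weights} and the objective trace.
#' @export
weightedConsensus <- function(collection, lambda = 0.1, K = NULL,
                              tol = 1e-8, maxIter = 100L, seed = 1L,
                              sparsify = 0.01, maxN = 20000L) {
  if (lambda <= 0) stop("lambda must be > 0")
  L <- if (is(collection, "LabelingCollection")) labelMatrix(collection)
       else as.matrix(collection)
  N <- nrow(L); M <- ncol(L)
  if (N > maxN)
    stop(sprintf(
      "N = %d exceeds the dense-storage cap (%d): the N x N co-association matrices grow quadratically in memory",
      N, maxN))
  ids <- rownames(L)
  if (is.null(ids)) ids <- as.character(seq_len(N))

  ## P x M binary matrix of per-pair co-association votes (i < j pairs)
  B <- vapply(seq_len(M), function(m) upperVec(coassociationMatrix(L[, m])),
              numeric(N * (N - 1) / 2))
  B <- matrix(B, ncol = M)

  fit <- wjsdOptimize(B, lambda, tol, maxIter)

  S <- matrix(0, N, N)
  S[upper.tri(S)] <- fit$s
  S <- S + t(S)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)

  if (!is.null(K)) {
    part <- resolutionSearch(makeLeidenPartitioner(S, seed = seed,
                                                   sparsify = sparsify),
                             targetK = K)
    labels <- part$labels
  } else {
    labels <- leidenPartition(S, resolution = 1, seed = seed,
                              sparsify = sparsify)
  }
  w <- fit$w
  names(w) <- colnames(L)
  new("ConsensusResult",
      labels = denseRelabel(labels), obsIds = ids,
      K = if (is.null(K)) NA_integer_ else as.integer(K),
      algorithm = "weighted", seed = as.integer(seed),
      objectiveTrace = fit$trace, weights = w, converged = fit$converged)
}

## alternating minimization on the pair-vote matrix B (P x M binary)
wjsdOptimize <- function(B, lambda, tol = 1e-8, maxIter = 100L) {
  M <- ncol(B)
  w <- rep(1 / M, M)
  s <- as.vector(B %*% w)  # init: unweighted co-association average
  trace <- numeric(); converged <- FALSE
  prev <- Inf
  for (iter in seq_len(maxIter)) {
    ## (a) S-step: per-entry 1-D convex minimization; entries share the
    ## solution through their weighted vote, so solve per unique vote
    vote <- as.vector(B %*% w)
    key <- round(vote, 12)
    uk <- unique(key)
    sol <- vapply(uk, solveEntry, numeric(1))
    s <- sol[match(key, uk)]
    ## (b) omega-step: closed-form softmax of the divergences
    D <- vapply(seq_len(M), function(m)
      sum(bernoulliJSD(s, B[, m])), numeric(1))
    e <- exp(-(D - min(D)) / lambda)
    w <- e / sum(e)
    obj <- sum(w * D) + lambda * sum(ifelse(w > 0, w * log(w), 0))
    trace <- c(trace, obj)
    if (abs(prev - obj) < tol) { converged <- TRUE; break }
    prev <- obj
  }
  list(s = s, w = w, trace = trace, converged = converged,
       objective = trace[length(trace)], divergences = D)
}

#' Partition a consensus similarity matrix with Leiden
#'
#' Builds an undirected weighted graph from the off-diagonal entries of
#' S at or above \code{sparsify} and runs igraph's Leiden algorithm with
#' the modularity objective. Deterministic given \code{seed}.
#'
#' @param S symmetric similarity matrix with entries in \eqn{[0, 1]}.
#' @param resolution modularity resolution parameter.
#' @param seed integer seed.
#' @param sparsify edge-weight threshold (default 0.01).
#' @return Integer membership vector.
#' @export
leidenPartition <- function(S, resolution = 1, seed = 1L, sparsify = 0.01) {
  A <- S
  diag(A) <- 0
  A[A < sparsify] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  withSeed(seed, {
    part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 5)
  })
  as.integer(igraph::membership(part))
}

#' Bind a Leiden partitioner for resolution search
#'
#' @inheritParams leidenPartition
#' @return A function \code{f(resolution)} returning labels, suitable
#'   for [resolutionSearch()].
#' @export
makeLeidenPartitioner <- function(S, seed = 1L, sparsify = 0.01) {
  force(S); force(seed); force(sparsify)
  function(resolution) leidenPartition(S, resolution = resolution,
                                       seed = seed, sparsify = sparsify)
}

#' Binary search over a resolution parameter for a target cluster count
#'
#' Assumes the partitioner's cluster count is non-decreasing in the
#' resolution. Searches \code{bounds} (doubling the upper bound up to 3
#' times, and halving the lower bound up to 3 times, when the target
#' lies outside); returns the first resolution achieving exactly
#' \code{targetK}, otherwise the evaluated labels whose cluster count is
#' nearest to the target (ties favor fewer clusters) with
#' \code{achieved = FALSE} and a warning.
#'
#' @param partitioner function \code{f(resolution)} returning a label
#'   vector (deterministic; bind graph and seed, e.g. with
#'   [makeLeidenPartitioner()]).
#' @param targetK desired number of clusters.
#' @param bounds numeric (lo, hi) resolution interval, lo < hi.
#' @param maxIter bisection cap (default 30).
#' @return A list: \code{resolution}, \code{labels}, \code{achievedK},
#'   \code{achieved}.
#' @export
resolutionSearch <- function(partitioner, targetK, bounds = c(0.05, 8),
                             maxIter = 30L) {
  stopifnot(bounds[1] < bounds[2], targetK >= 1)
  evalAt <- function(r) {
    labels <- partitioner(r)
    list(resolution = r, labels = labels, k = length(unique(labels)))
  }
  tried <- list()
  remember <- function(e) { tried[[length(tried) + 1L]] <<- e; e }

  lo <- remember(evalAt(bounds[1]))
  if (lo$k == targetK)
    return(list(resolution = lo$resolution, labels = lo$labels,
                achievedK = lo$k, achieved = TRUE))
  for (i in seq_len(3)) {
    if (lo$k < targetK) break
    lo <- remember(evalAt(lo$resolution / 2))
    if (lo$k == targetK)
      return(list(resolution = lo$resolution, labels = lo$labels,
                  achievedK = lo$k, achieved = TRUE))
  }
  hi <- remember(evalAt(bounds[2]))
  for (i in seq_len(3)) {
    if (hi$k >= targetK) break
    hi <- remember(evalAt(hi$resolution * 2))
  }
  if (hi$k == targetK)
    return(list(resolution = hi$resolution, labels = hi$labels,
                achievedK = hi$k, achieved = TRUE))

  if (lo$k < targetK && targetK < hi$k) {
    for (i in seq_len(maxIter)) {
      mid <- remember(evalAt((lo$resolution + hi$resolution) / 2))
      if (mid$k == targetK)
        return(list(resolution = mid$resolution, labels = mid$labels,
                    achievedK = mid$k, achieved = TRUE))
      if (mid$k < targetK) lo <- mid else hi <- mid
      if (hi$resolution - lo$resolution < 1e-9) break
    }
  }
  ## nearest fallback: smallest |k - target|, ties -> fewer clusters
  ks <- vapply(tried, `[[`, numeric(1), "k")
  pick <- order(abs(ks - targetK), ks)[1L]
  best <- tried[[pick]]
  warning(sprintf(
    "target cluster count %d not reachable in the searched resolution range; returning nearest (%d clusters)",
    targetK, best$k))
  list(resolution = best$resolution, labels = best$labels,
       achievedK = best$k, achieved = FALSE)
}
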