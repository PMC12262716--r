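## Hamming distances of every row of L to one mode vector
hammingToMode <- function(L, mode) {
  rowSums(L != matrix(mode, nrow(L), ncol(L), byrow = TRUE))
}

## column-wise modal label of a block of rows; ties -> smallest code
columnModes <- function(L, idx) {
  vapply(seq_len(ncol(L)), function(j) {
    t <- tabulate(L[idx, j], nbins = max(L[, j]))
    which.max(t)  # which.max returns the first (smallest) maximizer
  }, integer(1))
}

kmodesObjective <- function(L, modes, assign) {
  sum(vapply(seq_len(nrow(modes)), function(g) {
    idx <- which(assign == g)
    if (!length(idx)) return(0)
    sum(hammingToMode(L[idx, , drop = FALSE], modes[g, ]))
  }, numeric(1)))
}

kmodesRun <- function(L, K, maxIter) {
  N <- nrow(L)
  ## Huang-style init: sample K distinct rows as initial modes
  uniq <- which(!duplicated(asplit(L, 1)))
  pick <- if (length(uniq) >= K) {
    uniq[sample.int(length(uniq), K)]
  } else {
    rest <- setdiff(seq_len(N), uniq)
    c(uniq, rest[sample.int(length(rest), K - length(uniq))])
  }
  modes <- L[pick, , drop = FALSE]

  assign <- integer(N)
  trace <- numeric()
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    D <- vapply(seq_len(K), function(g) hammingToMode(L, modes[g, ]),
                numeric(N))
    D <- matrix(D, nrow = N)
    newAssign <- max.col(-D, ties.method = "first")
    ## empty-cluster repair: reseed from the row farthest from its mode
    repeat {
      empty <- setdiff(seq_len(K), unique(newAssign))
      if (!length(empty)) break
      cur <- D[cbind(seq_len(N), newAssign)]
      donor <- which.max(cur)
      message(sprintf("kmodes: reseeding empty cluster %d from row %d",
                      empty[1L], donor))
      modes[empty[1L], ] <- L[donor, ]
      D[, empty[1L]] <- hammingToMode(L, modes[empty[1L], ])
      newAssign <- max.col(-D, ties.method = "first")
    }
    modes <- t(vapply(seq_len(K), function(g) columnModes(L, which(newAssign == g)),
                      integer(ncol(L))))
    if (ncol(L) == 1L) modes <- matrix(modes, ncol = 1L)
    obj <- kmodesObjective(L, modes, newAssign)
    trace <- c(trace, obj)
    if (identical(newAssign, assign)) { converged <- TRUE; break }
    assign <- newAssign
  }
  list(assign = assign, objective = trace[length(trace)], trace = trace,
       converged = converged)
}

#' K-modes consensus clustering
#'
#' Treats the N x M matrix of base-clustering labels as categorical data
#' and partitions its rows into K groups minimizing the total Hamming
#' distance to group-specific mode vectors (the categorical analogue of
#' k-means). Each base clustering contributes equally; labels are purely
#' nominal. The best of \code{nStarts} random restarts is returned;
#' within a run the objective is non-increasing.
#'
#' @param collection a \linkS4class{LabelingCollection} or integer label
#'   matrix.
#' @param K number of consensus clusters, \code{1 <= K <= N}.
#' @param nStarts random restarts (default 10).
#' @param seed integer seed; results are bit-identical for equal seeds.
#' @param maxIter iteration cap per restart (default 100).
#' @return A \linkS4class{ConsensusResult}.
#' @export
kmodesConsensus <- function(collection, K, nStarts = 10L, seed = 1L,
                            maxIter = 100L) {
  L <- if (is(collection, "LabelingCollection")) labelMatrix(collection)
       else as.matrix(collection)
  N <- nrow(L)
  K <- as.integer(K)
  if (K < 1L || K > N) stop("K must satisfy 1 <= K <= N")
  ids <- rownames(L)
  if (is.null(ids)) ids <- as.character(seq_len(N))

  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nStarts)) {
      run <- kmodesRun(L, K, maxIter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  new("ConsensusResult",
      labels = denseRelabel(best$assign), obsIds = ids, K = K,
      algorithm = "kmodes", seed = as.integer(seed),
      objectiveTrace = best$trace, weights = numeric(),
      converged = best$converged)
}

## relabel codes by order of first appearance -> dense, deterministic
denseRelabel <- function(x) {
  match(x, unique(x))
}

## evaluate expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
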