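logSumExpRows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

lcaRun <- function(L, K, tol, maxIter, pseudocount) {
  N <- nrow(L); M <- ncol(L)
  Km <- apply(L, 2L, max)
  ## random soft initialization of responsibilities
  R <- matrix(stats::runif(N * K), N, K)
  R <- R / rowSums(R)

  ## Dirichlet(1 + pseudocount) prior on each conditional row; EM on the
  ## resulting log-posterior is monotone (the observed-data likelihood
  ## alone need not be under MAP updates)
  logPrior <- function(theta) pseudocount * sum(vapply(theta, function(th)
    sum(log(th)), numeric(1)))

  pi <- NULL; theta <- NULL
  trace <- numeric(); converged <- FALSE
  prev <- -Inf
  for (iter in seq_len(maxIter)) {
    ## M-step
    pi <- colMeans(R)
    pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
    theta <- vector("list", M)
    for (m in seq_len(M)) {
      th <- matrix(0, K, Km[m])
      for (j in seq_len(Km[m])) {
        sel <- L[, m] == j
        th[, j] <- colSums(R[sel, , drop = FALSE])
      }
      th <- th + pseudocount
      theta[[m]] <- th / rowSums(th)
    }
    ## E-step: log P(x_i | k) + log pi_k
    lp <- matrix(log(pi), N, K, byrow = TRUE)
    for (m in seq_len(M))
      lp <- lp + t(log(theta[[m]])[, L[, m], drop = FALSE])
    norm <- logSumExpRows(lp)
    if (any(!is.finite(norm))) stop("non-finite likelihood in LCA EM")
    R <- exp(lp - norm)
    obj <- sum(norm) + logPrior(theta)
    trace <- c(trace, obj)
    if (iter > 1L && obj - prev < tol) { converged <- TRUE; break }
    prev <- obj
  }
  logLik <- sum(norm)
  list(R = R, pi = pi, theta = theta, logLik = logLik,
       objective = trace[length(trace)], trace = trace, converged = converged)
}

#' Latent class analysis consensus clustering
#'
#' Fits a categorical mixture by EM: an unobserved latent class (the
#' consensus cluster) generates the observed base-clustering labels,
#' which are conditionally independent given the class,
#' \eqn{P(x_i) = \sum_k \pi_k \prod_m \theta_{mk,x_{im}}}. Unlike the
#' distance-based K-modes, disagreement between base clusterings is
#' absorbed by the method-specific conditionals \eqn{\theta}. Updates
#' use a Dirichlet pseudocount on \eqn{\theta} (MAP); the reported
#' objective trace is the penalized log-likelihood, which is
#' non-decreasing every iteration. The consensus label is the maximum
#' a-posteriori class; the best of \code{nStarts} restarts (by final
#' objective) is returned.
#'
#' @inheritParams kmodesConsensus
#' @param tol convergence threshold on the objective gain (default 1e-8).
#' @param maxIter EM iteration cap per restart (default 500).
#' @param pseudocount Dirichlet smoothing added to the conditional
#'   frequency updates (default 0.1).
#' @return A list with \code{result} (a \linkS4class{ConsensusResult})
#'   and \code{model} (an \linkS4class{LcaModel}).
#' @export
lcaConsensus <- function(collection, K, nStarts = 10L, seed = 1L,
                         tol = 1e-8, maxIter = 500L, pseudocount = 0.1) {
  L <- if (is(collection, "LabelingCollection")) labelMatrix(collection)
       else as.matrix(collection)
  N <- nrow(L)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  nPatterns <- nrow(unique(L))
  if (K > nPatterns)
    warning(sprintf("K = %d exceeds the %d distinct label patterns; some latent classes may stay empty",
                    K, nPatterns))
  ids <- rownames(L)
  if (is.null(ids)) ids <- as.character(seq_len(N))

  ## M = 1 is non-identifiable (collapsed and separating mixtures have
  ## equal likelihood, and the smoothing prior favors the collapse):
  ## return the EM fixed point seeded at the column itself, so a single
  ## base clustering is its own consensus
  if (ncol(L) == 1L && K == max(L[, 1L]))
    return(lcaDegenerateSingle(L, K, ids, seed, pseudocount))

  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nStarts)) {
      run <- lcaRun(L, K, tol, maxIter, pseudocount)
      if (is.null(best) || run$objective > best$objective) best <- run
    }
  })
  labels <- max.col(best$R, ties.method = "first")
  result <- new("ConsensusResult",
                labels = denseRelabel(labels), obsIds = ids, K = K,
                algorithm = "lca", seed = as.integer(seed),
                objectiveTrace = best$trace, weights = numeric(),
                converged = best$converged)
  model <- new("LcaModel", classPriors = best$pi,
               conditionals = best$theta, logLik = best$logLik)
  list(result = result, model = model)
}

## one M-step + E-step from one-hot responsibilities at the observed
## column: a fixed point of the EM map for the single-column model
lcaDegenerateSingle <- function(L, K, ids, seed, pseudocount) {
  x <- L[, 1L]
  N <- length(x)
  R <- matrix(0, N, K)
  R[cbind(seq_len(N), x)] <- 1
  pi <- colMeans(R)
  th <- matrix(0, K, K)
  for (j in seq_len(K)) th[, j] <- colSums(R[x == j, , drop = FALSE])
  th <- th + pseudocount
  th <- th / rowSums(th)
  lp <- matrix(log(pi), N, K, byrow = TRUE) + t(log(th)[, x, drop = FALSE])
  norm <- logSumExpRows(lp)
  result <- new("ConsensusResult",
                labels = denseRelabel(x), obsIds = ids, K = K,
                algorithm = "lca", seed = as.integer(seed),
                objectiveTrace = sum(norm) + pseudocount * sum(log(th)),
                weights = numeric(), converged = TRUE)
  model <- new("LcaModel", classPriors = pi, conditionals = list(th),
               logLik = sum(norm))
  list(result = result, model = model)
}
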