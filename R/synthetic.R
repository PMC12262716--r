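#' Construct a NoiseSpec
#'
#' Recipe of perturbations turning a ground-truth tissue labeling into
#' one synthetic "base clustering". Applied in order: merges, splits,
#' boundary jitter, independent label flips, optional label permutation.
#'
#' @param flipRate per-observation probability in [0, 1) of reassignment
#'   to a uniformly random other label (salt-and-pepper noise).
#' @param jitterRadius lattice-step radius around domain boundaries (on
#'   the 4-neighbor grid graph) within which observations may jitter.
#' @param jitterProb probability that an eligible observation is
#'   reassigned to its nearest other domain (boundary disagreement).
#' @param splits domain ids split in two at their coordinate median
#'   (granularity increase).
#' @param merges list of domain-id pairs merged into one (granularity
#'   decrease).
#' @param permuteLabels randomly permute the label codes (methods name
#'   clusters arbitrarily).
#' @param seed integer.
#' @return A \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(flipRate = 0, jitterRadius = 0, jitterProb = 0,
                      splits = integer(), merges = list(),
                      permuteLabels = FALSE, seed = 1L) {
  new("NoiseSpec", flipRate = as.numeric(flipRate),
      jitterRadius = as.numeric(jitterRadius),
      jitterProb = as.numeric(jitterProb),
      splits = as.integer(splits),
      merges = lapply(merges, as.integer),
      permuteLabels = isTRUE(permuteLabels), seed = as.integer(seed))
}

#' Generate a lattice tissue with known spatial domains
#'
#' Observations form an \code{nRows} x \code{nCols} square grid with
#' unit spacing (x = column, y = row). The \code{"layers"} layout cuts
#' the rows into horizontal bands of near-equal height (layered-cortex
#' style); \code{"blocks"} tiles the grid with rectangles. Every domain
#' is a connected, non-empty set on the 4-neighbor lattice. Fully
#' deterministic.
#'
#' @param layout \code{"layers"} or \code{"blocks"}.
#' @param nRows,nCols lattice dimensions.
#' @param nDomains number of ground-truth domains.
#' @param seed integer recorded in the object (the layout itself is
#'   deterministic).
#' @return A \linkS4class{SyntheticTissue}.
#' @examples
#' tissue <- generateTissue("layers", 12, 10, 4)
#' table(groundTruth(tissue)@labels)
#' @export
generateTissue <- function(layout = c("layers", "blocks"), nRows, nCols,
                           nDomains, seed = 1L) {
  layout <- match.arg(layout)
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  nDomains <- as.integer(nDomains)
  N <- nRows * nCols
  if (nDomains < 1L) stop("nDomains must be >= 1")

  row <- rep(seq_len(nRows), each = nCols)
  col <- rep(seq_len(nCols), times = nRows)

  if (layout == "layers") {
    if (nDomains > nRows)
      stop(sprintf("layers layout needs nDomains <= nRows (%d > %d)",
                   nDomains, nRows))
    breaks <- round(seq(0, nRows, length.out = nDomains + 1L))
    gt <- findInterval(row, breaks, left.open = TRUE)
  } else {
    if (nDomains > N)
      stop(sprintf("blocks layout needs nDomains <= nRows * nCols"))
    tile <- blockTiling(nDomains, nRows, nCols)
    rBreaks <- round(seq(0, nRows, length.out = tile[1L] + 1L))
    cBreaks <- round(seq(0, nCols, length.out = tile[2L] + 1L))
    rBand <- findInterval(row, rBreaks, left.open = TRUE)
    cBand <- findInterval(col, cBreaks, left.open = TRUE)
    gt <- (rBand - 1L) * tile[2L] + cBand
  }

  ids <- sprintf("s%0*d", nchar(N), seq_len(N))
  coords <- cbind(x = as.numeric(col), y = as.numeric(row))
  rownames(coords) <- ids
  new("SyntheticTissue", coords = coords, gtLabels = as.integer(gt),
      layout = layout, nDomains = nDomains, nRows = nRows, nCols = nCols,
      seed = as.integer(seed))
}

## rectangular tiling (rBlocks x cBlocks = nDomains) closest to square
blockTiling <- function(nDomains, nRows, nCols) {
  divs <- which(nDomains %% seq_len(nDomains) == 0L)
  cand <- cbind(r = divs, c = nDomains %/% divs)
  cand <- cand[cand[, 1L] <= nRows & cand[, 2L] <= nCols, , drop = FALSE]
  if (!nrow(cand))
    stop("no rectangular tiling of nDomains fits the lattice")
  cand[order(abs(cand[, 1L] - cand[, 2L]), cand[, 1L])[1L], ]
}

## lattice-step distance of every observation to the nearest domain
## boundary (BFS on the 4-neighbor grid from all border spots); also
## returns, per observation, the label of the nearest foreign domain
latticeBorderDistance <- function(labels, nRows, nCols) {
  idx <- matrix(seq_len(nRows * nCols), nrow = nRows, ncol = nCols,
                byrow = TRUE)
  lab <- matrix(labels, nrow = nRows, ncol = nCols, byrow = TRUE)
  dist <- matrix(Inf, nRows, nCols)
  foreign <- matrix(NA_integer_, nRows, nCols)

  ## seed: spots with a 4-neighbor of a different label get distance 1
  ## and that neighbor's label (smallest label on ties, row-major scan)
  frontier <- integer()
  for (r in seq_len(nRows)) for (c in seq_len(nCols)) {
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nRows & nb[, 2] >= 1 & nb[, 2] <= nCols,
             , drop = FALSE]
    nbl <- lab[nb]
    diff <- nbl[nbl != lab[r, c]]
    if (length(diff)) {
      dist[r, c] <- 1
      foreign[r, c] <- min(diff)
      frontier <- c(frontier, idx[r, c])
    }
  }
  ## BFS outward: distance grows by one lattice step per ring
  d <- 1
  while (length(frontier)) {
    nxt <- integer()
    for (p in frontier) {
      r <- (p - 1) %/% nCols + 1; c <- (p - 1) %% nCols + 1
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nRows & nb[, 2] >= 1 &
                 nb[, 2] <= nCols, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        rr <- nb[q, 1]; cc <- nb[q, 2]
        if (dist[rr, cc] > d + 1) {
          dist[rr, cc] <- d + 1
          foreign[rr, cc] <- foreign[r, c]
          nxt <- c(nxt, idx[rr, cc])
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  ## back to row-major observation order
  list(dist = as.vector(t(dist)), foreign = as.vector(t(foreign)))
}

#' Perturb a tissue's ground truth into a noisy base clustering
#'
#' Emulates the label output of one spatially aware clustering method:
#' granularity mismatch (domain merges/splits), boundary disagreement
#' (jitter near domain borders), salt-and-pepper noise (independent
#' label flips) and arbitrary cluster naming (label permutation), in
#' that order. Deterministic given the spec's seed.
#'
#' @param tissue a \linkS4class{SyntheticTissue}.
#' @param spec a \linkS4class{NoiseSpec}.
#' @param methodId,configId provenance for the resulting labeling;
#'   \code{configId} defaults to a compact rendering of the spec.
#' @return A \linkS4class{SpatialLabeling}.
#' @export
perturbLabeling <- function(tissue, spec, methodId = "synthetic",
                            configId = NULL) {
  stopifnot(is(tissue, "SyntheticTissue"), is(spec, "NoiseSpec"))
  lab <- tissue@gtLabels
  if (is.null(configId))
    configId <- sprintf("flip%.3g_jit%g:%.3g_sp%d_mg%d_perm%d_seed%d",
                        spec@flipRate, spec@jitterRadius, spec@jitterProb,
                        length(spec@splits), length(spec@merges),
                        as.integer(spec@permuteLabels), spec@seed)

  withSeed(spec@seed, {
    ## merges: map the pair's larger id onto the smaller
    for (p in spec@merges) {
      if (!all(p %in% lab)) stop("merge references a missing domain")
      lab[lab == max(p)] <- min(p)
    }
    ## splits: cut a domain at the median of its wider coordinate axis
    nextCode <- max(lab)
    for (s in spec@splits) {
      idx <- which(lab == s)
      if (!length(idx)) stop("split references a missing domain")
      xy <- tissue@coords[idx, , drop = FALSE]
      axis <- if (diff(range(xy[, 1])) >= diff(range(xy[, 2]))) 1L else 2L
      cut <- stats::median(xy[, axis])
      nextCode <- nextCode + 1L
      lab[idx[xy[, axis] > cut]] <- nextCode
    }
    ## boundary jitter on the (possibly merged/split) domains
    if (spec@jitterRadius > 0 && spec@jitterProb > 0) {
      bd <- latticeBorderDistance(lab, tissue@nRows, tissue@nCols)
      eligible <- which(bd$dist <= spec@jitterRadius)
      hit <- eligible[stats::runif(length(eligible)) < spec@jitterProb]
      lab[hit] <- bd$foreign[hit]
    }
    ## independent flips to a uniformly random *other* label
    if (spec@flipRate > 0) {
      alphabet <- sort(unique(lab))
      if (length(alphabet) > 1L) {
        hit <- which(stats::runif(length(lab)) < spec@flipRate)
        if (length(hit)) {
          shift <- sample.int(length(alphabet) - 1L, length(hit),
                              replace = TRUE)
          cur <- match(lab[hit], alphabet)
          lab[hit] <- alphabet[1L + (cur - 1L + shift) %% length(alphabet)]
        }
      }
    }
    if (spec@permuteLabels) {
      alphabet <- sort(unique(lab))
      perm <- sample(alphabet)
      lab <- perm[match(lab, alphabet)]
    }
  })
  SpatialLabeling(rownames(tissue@coords), tissue@coords, lab,
                  methodId = methodId, configId = configId)
}

#' Generate a collection of noisy base clusterings of one tissue
#'
#' One perturbed labeling per \linkS4class{NoiseSpec}, assembled with
#' [buildCollection()]; the ground-truth labeling is returned alongside.
#'
#' @param tissue a \linkS4class{SyntheticTissue}.
#' @param specs list of \linkS4class{NoiseSpec} objects (one per column).
#' @param methodIds optional character of per-column method names
#'   (defaults to \code{method01, method02, ...}).
#' @return A list with \code{collection}
#'   (\linkS4class{LabelingCollection}) and \code{gt}
#'   (\linkS4class{SpatialLabeling}).
#' @export
generateCollection <- function(tissue, specs, methodIds = NULL) {
  M <- length(specs)
  stopifnot(M >= 1L)
  if (is.null(methodIds))
    methodIds <- sprintf("method%02d", seq_len(M))
  stopifnot(length(methodIds) == M)
  labelings <- lapply(seq_len(M), function(m)
    perturbLabeling(tissue, specs[[m]], methodId = methodIds[m]))
  list(collection = buildCollection(labelings), gt = groundTruth(tissue))
}

#' Per-granularity collections for a cluster-number sweep
#'
#' For each requested cluster count k, builds a collection of M noisy
#' base clusterings that all carry exactly k classes: at the tissue's
#' true granularity the columns are flip-noised copies of the ground
#' truth; at coarser k each column merges a randomly chosen set of
#' adjacent domain pairs (so columns disagree about which domains to
#' fuse); at finer k each column splits randomly chosen domains. Columns
#' whose noise happens to change the realized class count are rejected
#' and resampled (flip noise never removes a class at the rates used
#' here; the guard is for small tissues).
#'
#' @param tissue a \linkS4class{SyntheticTissue} (layers layout, so that
#'   adjacent-domain merges are well defined).
#' @param kValues integer cluster counts to cover.
#' @param M base clusterings per k.
#' @param flipRate flip noise applied to every column.
#' @param seed integer.
#' @return Named list (by k) of \linkS4class{LabelingCollection}s.
#' @export
granularityCollections <- function(tissue, kValues, M = 6L, flipRate = 0.05,
                                   seed = 1L) {
  kStar <- tissue@nDomains
  out <- vector("list", length(kValues))
  names(out) <- as.character(kValues)
  for (ki in seq_along(kValues)) {
    k <- kValues[ki]
    labelings <- vector("list", M)
    for (m in seq_len(M)) {
      colSeed <- (seed * 1000L + ki * 100L + m) %% .Machine$integer.max
      for (attempt in 1:25) {
        sp <- withSeed(colSeed + attempt * 31L, {
          if (k == kStar) {
            noiseSpec(flipRate = flipRate, seed = colSeed)
          } else if (k < kStar) {
            ## merge adjacent band pairs chosen at random, per column
            merges <- list()
            alive <- seq_len(kStar)
            for (i in seq_len(kStar - k)) {
              j <- sample(length(alive) - 1L, 1L)
              merges[[i]] <- c(alive[j], alive[j + 1L])
              alive <- alive[-(j + 1L)]
            }
            noiseSpec(flipRate = flipRate, merges = merges, seed = colSeed)
          } else {
            splits <- sample(kStar, min(k - kStar, kStar))
            noiseSpec(flipRate = flipRate, splits = splits, seed = colSeed)
          }
        })
        cand <- perturbLabeling(tissue, sp,
                                methodId = sprintf("method%02d", m))
        if (length(cand@labelLevels) == k) break
        colSeed <- colSeed + 1000L
      }
      if (length(cand@labelLevels) != k)
        stop(sprintf("could not realize a %d-class labeling", k))
      labelings[[m]] <- cand
    }
    out[[ki]] <- buildCollection(labelings)
  }
  out
}
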