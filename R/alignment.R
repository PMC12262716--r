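#' Align label codes across base clusterings
#'
#' Each non-reference column's codes are bijectively remapped to
#' maximize the total overlap with the reference column, the optimum of
#' the assignment problem on the confusion matrix (Hungarian method via
#' \code{clue::solve_LSAP}). When the column has more classes than the
#' reference, the confusion matrix is padded with zero-overlap dummy
#' classes and surplus classes receive fresh codes beyond the reference
#' alphabet (in ascending order of their original code, so the mapping
#' is deterministic).
#'
#' @param labels an N x M integer label matrix (dense per-column codes)
#'   or a \linkS4class{LabelingCollection}.
#' @param reference column index of the reference labeling (default 1).
#' @return An integer matrix of the same shape; the reference column is
#'   unchanged.
#' @export
alignLabelings <- function(labels, reference = 1L) {
  if (is(labels, "LabelingCollection")) labels <- labelMatrix(labels)
  stopifnot(is.matrix(labels), ncol(labels) >= 1L)
  reference <- as.integer(reference)
  ref <- labels[, reference]
  Kr <- max(ref)
  out <- labels
  for (j in seq_len(ncol(labels))) {
    if (j == reference) next
    out[, j] <- alignToReference(ref, labels[, j], Kr)
  }
  out
}

## remap codes of `other` to maximize overlap with `ref`
alignToReference <- function(ref, other, Kr = max(ref)) {
  Ko <- max(other)
  C <- matrix(0, nrow = Ko, ncol = Kr)
  tab <- table(factor(other, levels = seq_len(Ko)),
               factor(ref, levels = seq_len(Kr)))
  C[] <- tab
  side <- max(Ko, Kr)
  Cp <- matrix(0, side, side)
  Cp[seq_len(Ko), seq_len(Kr)] <- C
  sol <- clue::solve_LSAP(Cp, maximum = TRUE)
  mapping <- integer(Ko)
  nextFresh <- Kr
  for (o in seq_len(Ko)) {
    a <- sol[o]
    if (a <= Kr) {
      mapping[o] <- a
    } else {
      nextFresh <- nextFresh + 1L
      mapping[o] <- nextFresh
    }
  }
  mapping[other]
}

#' Cross-method entropy field
#'
#' For every choice of reference column r, all columns are aligned to r
#' with [alignLabelings()] and the per-observation Shannon entropy
#' across the M aligned labels is computed; the field is the mean of
#' these M per-reference entropy maps. High values mark observations on
#' which the base clusterings disagree even after optimal label
#' matching. Reported in nats; the optional normalized variant divides
#' by \code{log} of the largest aligned alphabet.
#'
#' @param collection a \linkS4class{LabelingCollection} (or integer
#'   label matrix) with at least two columns.
#' @param normalized divide by the log alphabet bound (default FALSE).
#' @return An \linkS4class{EntropyField}.
#' @export
crossMethodEntropy <- function(collection, normalized = FALSE) {
  L <- if (is(collection, "LabelingCollection")) labelMatrix(collection)
       else as.matrix(collection)
  ids <- rownames(L)
  M <- ncol(L)
  if (M < 2L) stop("cross-method entropy needs at least two base clusterings")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(L)))
  N <- nrow(L)
  acc <- numeric(N)
  maxAlpha <- 2L
  for (r in seq_len(M)) {
    A <- alignLabelings(L, reference = r)
    nmax <- max(A)
    maxAlpha <- max(maxAlpha, nmax)
    acc <- acc + vapply(seq_len(N), function(i) entropyCodes(A[i, ], nmax),
                        numeric(1))
  }
  vals <- acc / M
  bound <- log(maxAlpha)
  if (normalized) {
    vals <- vals / bound
    bound <- 1
  }
  new("EntropyField", obsIds = ids, values = vals, alphabetBound = bound)
}
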