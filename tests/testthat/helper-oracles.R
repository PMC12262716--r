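## Independent oracles used across the suite. These deliberately avoid
## the package's own code paths.

## Shannon entropy by direct evaluation of the defining formula
entropyOracle <- function(labels) {
  counts <- as.numeric(table(labels))
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

## ARI from explicit enumeration of all C(N, 2) observation pairs
ariPairOracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  ## identical set partitions <=> co-membership agrees on every pair
  if (denom == 0) return(if (n10 + n01 == 0) 1 else 0)
  2 * (n11 * n00 - n10 * n01) / denom
}

## all permutations of 1..n (n <= 7)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

## maximum total overlap of `other` with `ref` over all injective code
## maps (exhaustive search; small alphabets only)
alignmentOverlapOracle <- function(ref, other) {
  Kr <- max(ref); Ko <- max(other)
  side <- max(Kr, Ko)
  perms <- permutations(side)          # maps padded-other -> padded-ref
  best <- -Inf
  for (p in seq_len(nrow(perms))) {
    m <- perms[p, ]
    best <- max(best, sum(m[other] == ref))
  }
  as.integer(best)
}

## exhaustive K-modes optimum: minimize total Hamming distance to
## per-group column modes over all K^N assignments
kmodesOracle <- function(L, K) {
  N <- nrow(L)
  stopifnot(K^N <= 1e6)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  for (r in seq_len(nrow(grid))) {
    assign <- grid[r, ]
    obj <- 0
    for (g in seq_len(K)) {
      idx <- which(assign == g)
      if (!length(idx)) next
      mode <- apply(L[idx, , drop = FALSE], 2, function(x) {
        t <- tabulate(x, nbins = max(L))
        which.max(t)
      })
      obj <- obj + sum(L[idx, , drop = FALSE] !=
                         matrix(mode, length(idx), ncol(L), byrow = TRUE))
    }
    if (obj < best) best <- obj
  }
  best
}

## independently written Bernoulli JSD (log-space arithmetic differs
## from the package's vectorized form)
jsdOracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a, b) {
    s <- 0
    if (a > 0) s <- s + a * log(a / b)
    if (a < 1) s <- s + (1 - a) * log((1 - a) / (1 - b))
    s
  }
  0.5 * term(p, m) + 0.5 * term(q, m)
}

## a small labeled lattice collection used by several tests
makeToyCollection <- function(M = 4, flipRate = 0.05, seed = 1,
                              nRows = 12, nCols = 10, nDomains = 4,
                              permute = TRUE, methodIds = NULL) {
  tissue <- generateTissue("layers", nRows, nCols, nDomains, seed = seed)
  specs <- lapply(seq_len(M), function(m)
    noiseSpec(flipRate = flipRate, permuteLabels = permute,
              seed = seed * 100 + m))
  generateCollection(tissue, specs, methodIds = methodIds)
}

## plain SpatialLabeling on a 1-D chain (y = 0), unit spacing
chainLabeling <- function(labels, methodId = "chain") {
  n <- length(labels)
  SpatialLabeling(sprintf("c%02d", seq_len(n)),
                  cbind(x = as.numeric(seq_len(n)), y = 0),
                  labels, methodId = methodId)
}
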