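## collection with controllable modal class fractions
imbalancedCollection <- function(fracs, n = 100) {
  labelings <- lapply(seq_along(fracs), function(j) {
    big <- round(fracs[j] * n)
    lab <- c(rep(1, big), rep(2:4, length.out = n - big))
    SpatialLabeling(sprintf("o%03d", 1:n), cbind(seq_len(n), 0), lab,
                    methodId = sprintf("m%d", j))
  })
  buildCollection(labelings)
}

test_that("imbalance filter drops >90% columns and keeps the boundary", {
  coll <- imbalancedCollection(c(0.91, 0.90, 0.25))
  out <- filterImbalanced(coll, threshold = 0.9)
  expect_identical(removedColumns(out$report)$methodId, "m1")
  expect_identical(removedColumns(out$report)$reason, "imbalance")
  expect_identical(keptColumns(out$report)$methodId, c("m2", "m3"))
  expect_identical(ncol(out$collection), 2L)
})

test_that("imbalance filter errors when nothing survives", {
  coll <- imbalancedCollection(c(0.95, 0.99))
  expect_error(filterImbalanced(coll, 0.9), "higher threshold")
})

test_that("imbalance filter is idempotent", {
  coll <- imbalancedCollection(c(0.91, 0.5, 0.3))
  once <- filterImbalanced(coll, 0.9)$collection
  twice <- filterImbalanced(once, 0.9)
  expect_identical(ncol(twice$collection), ncol(once))
  expect_identical(nrow(removedColumns(twice$report)), 0L)
})

## collection with controlled per-column provenance for ranking tests
provCollection <- function(methods, seed = 1) {
  gc <- makeToyCollection(M = length(methods), flipRate = 0.05, seed = seed,
                          methodIds = methods)
  gc$collection
}

test_that("selectSmoothest dedupes per algorithm before ranking", {
  coll <- provCollection(c("alg1", "alg1", "alg1"))
  se <- c(0.3, 0.2, 0.4)
  names(se) <- colnames(coll)
  expect_warning(out <- selectSmoothest(coll, se, n = 2, dedupe = TRUE),
                 "keeping all")
  expect_identical(ncol(out$collection), 1L)
  kept <- keptColumns(out$report)
  expect_identical(kept$column, colnames(coll)[2])  # the 0.2 column
  expect_identical(sort(unique(removedColumns(out$report)$reason)),
                   "duplicate-algorithm")
})

test_that("selectSmoothest keeps the n lowest-SE columns", {
  coll <- provCollection(sprintf("alg%d", 1:6))
  se <- c(0.5, 0.1, 0.4, 0.2, 0.6, 0.3)
  names(se) <- colnames(coll)
  out <- selectSmoothest(coll, se, n = 3, dedupe = TRUE)
  expect_setequal(keptColumns(out$report)$methodId,
                  c("alg2", "alg4", "alg6"))
  cut <- removedColumns(out$report)
  expect_identical(sort(cut$reason), rep("rank-cutoff", 3))
})

test_that("SE ties break by lexicographic provenance order", {
  coll <- provCollection(c("zeta", "alpha"))
  se <- c(0.25, 0.25)
  names(se) <- colnames(coll)
  out <- selectSmoothest(coll, se, n = 1, dedupe = FALSE)
  expect_identical(keptColumns(out$report)$methodId, "alpha")
})

test_that("selectSmoothest is idempotent", {
  coll <- provCollection(sprintf("alg%d", 1:5))
  se <- smoothnessScores(coll)
  once <- selectSmoothest(coll, se, n = 3, dedupe = TRUE)
  se2 <- se[colnames(once$collection)]
  twice <- selectSmoothest(once$collection, se2, n = 3, dedupe = TRUE)
  expect_identical(colnames(twice$collection), colnames(once$collection))
})

## synthetic agreement matrix with a planted concordant block
plantedAgreement <- function(blockIdx, M, hi = 0.8, lo = 0.1,
                             methods = sprintf("m%d", seq_len(M))) {
  v <- matrix(lo, M, M)
  v[blockIdx, blockIdx] <- hi
  diag(v) <- 1
  dimnames(v) <- list(methods, methods)
  new("AgreementMatrix", values = v, metric = "ARI",
      provenance = data.frame(methodId = methods,
                              configId = "default",
                              stringsAsFactors = FALSE))
}

test_that("concordanceBlock recovers a planted block", {
  ag <- plantedAgreement(1:4, M = 6)
  rep <- concordanceBlock(ag, nGroups = 2, minBlockSize = 3)
  expect_setequal(keptColumns(rep)$methodId, sprintf("m%d", 1:4))
  expect_identical(sort(unique(removedColumns(rep)$reason)), "out-of-block")
  ## exhaustive check: the winning block has maximal mean internal ARI
  ## over all 2-cuts of the tree
  grp <- blockAssignments(rep)
  v <- agreementValues(ag)
  means <- vapply(unique(grp), function(g) {
    idx <- which(grp == g)
    w <- v[idx, idx]
    if (length(idx) == 1) 1 else mean(w[upper.tri(w)])
  }, numeric(1))
  winner <- unique(grp[keptColumns(rep)$column])
  eligible <- unique(grp)[table(grp)[as.character(unique(grp))] >= 3]
  expect_identical(means[match(winner, unique(grp))],
                   max(means[match(eligible, unique(grp))]))
})

test_that("all-identical agreement collapses to one absorbing group", {
  ag <- plantedAgreement(1:5, M = 5, hi = 1, lo = 1)
  rep <- concordanceBlock(ag, nGroups = 2, minBlockSize = 3)
  ## the cut still produces 2 nominal groups, but the winner holds >= 3
  expect_gte(nrow(keptColumns(rep)), 3L)
})

test_that("singleton cuts error when minBlockSize > 1", {
  ag <- plantedAgreement(1:2, M = 4)
  expect_error(concordanceBlock(ag, nGroups = 4, minBlockSize = 2),
               "group sizes")
})

test_that("concordanceBlock is invariant to column reordering", {
  gc <- makeToyCollection(M = 6, flipRate = 0.1, seed = 13,
                          methodIds = sprintf("alg%d", 1:6))
  ag <- pairwiseAgreement(gc$collection)
  rep1 <- concordanceBlock(ag, nGroups = 2, minBlockSize = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  v <- agreementValues(ag)[perm, perm]
  ag2 <- new("AgreementMatrix", values = v, metric = "ARI",
             provenance = ag@provenance[perm, ])
  rep2 <- concordanceBlock(ag2, nGroups = 2, minBlockSize = 2)
  expect_setequal(keptColumns(rep1)$column, keptColumns(rep2)$column)
})

test_that("concordance block separates clean perturbations from noise", {
  ## {clean flip-0.08 copies of GT} u {random labelings}: the block must
  ## recover exactly the clean set
  for (seed in 1:5) {
    tissue <- generateTissue("layers", 12, 10, 4, seed = seed)
    clean <- lapply(1:5, function(m)
      perturbLabeling(tissue, noiseSpec(flipRate = 0.08, seed = seed * 50 + m),
                      methodId = sprintf("clean%d", m)))
    random <- lapply(1:3, function(m) {
      sl <- withr::with_seed(seed * 90 + m,
        SpatialLabeling(obsIds(tissue), spatialCoords(tissue),
                        sample(4, nrow(spatialCoords(tissue)), TRUE),
                        methodId = sprintf("rand%d", m)))
      sl
    })
    coll <- buildCollection(c(clean, random))
    rep <- concordanceBlock(pairwiseAgreement(coll), nGroups = 2,
                            minBlockSize = 3)
    expect_setequal(keptColumns(rep)$methodId, sprintf("clean%d", 1:5))
  }
})
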