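test_that("shannonEntropy matches hand-evaluated values", {
  expect_identical(shannonEntropy(rep("a", 4)), 0)
  expect_equal(shannonEntropy(c("a", "b")), log(2), tolerance = 1e-12)
  expect_equal(shannonEntropy(c("a", "a", "b", "c")),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannonEntropy(character()), "empty")
})

test_that("shannonEntropy is bounded by log(m), equality at uniformity", {
  set.seed(11)
  for (i in 1:30) {
    m <- sample(2:6, 1)
    v <- sample(m, sample(5:40, 1), replace = TRUE)
    h <- shannonEntropy(v)
    expect_gte(h, 0)
    expect_lte(h, log(length(unique(v))) + 1e-12)
  }
  expect_equal(shannonEntropy(rep(1:5, each = 3)), log(5), tolerance = 1e-12)
})

test_that("buildKnnGraph finds nearest neighbors on a 1-D chain", {
  g <- buildKnnGraph(cbind(c(0, 1, 2), 0), k = 1)
  expect_identical(neighborIndices(g), list(2L, 1L, 2L))
  expect_error(buildKnnGraph(cbind(c(0, 1, 2), 0), k = 3), "k must satisfy")
})

test_that("maxDistance filters neighbors after k-selection", {
  ## unit-spaced chain of 5; interior points keep both unit neighbors,
  ## ends lose their second-nearest (distance 2 > 1.5)
  g <- buildKnnGraph(cbind(0:4, 0), k = 2, maxDistance = 1.5)
  lens <- lengths(neighborIndices(g))
  expect_identical(lens, c(1L, 2L, 2L, 2L, 1L))
  expect_true(all(unlist(neighborDistances(g)) <= 1.5))
  ## exhaustive pairwise-distance oracle for the retained sets
  coords <- cbind(0:4, 0)
  for (i in 1:5) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], 5, 2, TRUE))^2))
    d[i] <- Inf
    expected <- which(rank(d, ties.method = "first") <= 2 & d <= 1.5)
    expect_setequal(neighborIndices(g)[[i]], expected)
  }
})

test_that("knn ties break by ascending observation-id order", {
  ## unit square: each corner has two neighbors at distance 1
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  rownames(coords) <- c("p1", "p2", "p3", "p4")
  g <- buildKnnGraph(coords, k = 1)
  ## p1's equidistant neighbors are p2 and p3 -> p2 wins (smaller id)
  expect_identical(neighborIndices(g)[[1]], 2L)
  expect_identical(neighborIndices(g)[[4]], 2L)  # p2 < p3
})

test_that("smoothness entropy is zero for constant labelings", {
  sl <- chainLabeling(rep("A", 8))
  f <- smoothnessEntropy(sl, k = 2)
  expect_identical(unname(entropyValues(f)), rep(0, 8))
  expect_identical(meanEntropy(f), 0)
})

test_that("smoothness entropy matches brute force on the 4-chain", {
  h <- -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3))
  ## adjacency neighborhoods (k = 2 within distance 1): interior spots
  ## see {A,A,B}/{B,B,A}, ends stay pure -> per-spot [0, h, h, 0]
  sl <- chainLabeling(c("A", "A", "B", "B"))
  g <- buildKnnGraph(spatialCoords(sl), k = 2, maxDistance = 1)
  f <- smoothnessEntropy(sl, g)
  expect_equal(unname(entropyValues(f)), c(0, h, h, 0), tolerance = 1e-12)
  expect_equal(meanEntropy(f), h / 2, tolerance = 1e-12)
  ## plain k = 2 (no cutoff): ends reach across distance 2, so every
  ## closed neighborhood is a 2:1 mix (brute-force enumeration)
  f2 <- smoothnessEntropy(sl, k = 2)
  expect_equal(unname(entropyValues(f2)), rep(h, 4), tolerance = 1e-12)
  ## k = 1 with equidistant interior ties: the ascending-id tie-break
  ## hands spot 3 its left (A-labeled) neighbor -> single mixed pair
  f1 <- smoothnessEntropy(sl, k = 1)
  expect_equal(unname(entropyValues(f1)), c(0, 0, log(2), 0),
               tolerance = 1e-12)
  ## tie-free uneven spacing: every nearest neighbor shares its label
  slU <- SpatialLabeling(sprintf("u%d", 1:4),
                         cbind(x = c(0, 1, 3, 4), y = 0),
                         c("A", "A", "B", "B"))
  expect_identical(meanEntropy(smoothnessEntropy(slU, k = 1)), 0)
})

test_that("smoothness entropy is invariant under label permutation", {
  gc <- makeToyCollection(M = 1, flipRate = 0.2, seed = 3)
  sl <- collectionLabeling(gc$collection, 1)
  permuted <- SpatialLabeling(obsIds(sl), spatialCoords(sl),
                              c(4, 2, 1, 3, 5)[labelCodes(sl)][
                                seq_along(labelCodes(sl))])
  g <- buildKnnGraph(spatialCoords(sl), k = 6)
  expect_equal(meanEntropy(smoothnessEntropy(sl, g)),
               meanEntropy(smoothnessEntropy(permuted, g)), tolerance = 1e-12)
})

test_that("majority smoothing does not increase smoothness entropy", {
  set.seed(5)
  tissue <- generateTissue("layers", 15, 12, 3)
  noisy <- perturbLabeling(tissue, noiseSpec(flipRate = 0.25, seed = 9))
  g <- buildKnnGraph(spatialCoords(noisy), k = 6)
  ## majority-smooth: each spot takes the modal label of its closed
  ## neighborhood
  lab <- labelCodes(noisy)
  smoothed <- vapply(seq_along(lab), function(i) {
    nb <- c(lab[i], lab[neighborIndices(g)[[i]]])
    as.integer(which.max(tabulate(nb, nbins = max(lab))))
  }, integer(1))
  slSmooth <- SpatialLabeling(obsIds(noisy), spatialCoords(noisy), smoothed)
  expect_lte(meanEntropy(smoothnessEntropy(slSmooth, g)),
             meanEntropy(smoothnessEntropy(noisy, g)))
})

test_that("borderMask flags exactly the domain boundaries", {
  expect_false(any(borderMask(chainLabeling(rep("A", 6)))))
  sl <- chainLabeling(c("A", "A", "B", "B"))
  ## adjacency neighbors (within distance 1): the two middle spots touch
  ## the A|B boundary
  g <- buildKnnGraph(spatialCoords(sl), k = 2, maxDistance = 1)
  expect_identical(unname(borderMask(sl, g)), c(FALSE, TRUE, TRUE, FALSE))
  ## k = 1 with equidistant ties: spot 2's tie-break neighbor is spot 1
  ## (same label), so only spot 3 sees across the boundary
  g1 <- buildKnnGraph(spatialCoords(sl), k = 1)
  expect_identical(unname(borderMask(sl, g1)), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("isolated observations are never border spots", {
  ## third point is far away: its k neighbors all get distance-filtered
  coords <- cbind(c(0, 1, 50), 0)
  rownames(coords) <- c("a", "b", "z")
  sl <- SpatialLabeling(rownames(coords), coords, c("A", "B", "A"))
  m <- borderMask(sl, k = 2, maxDistance = 1.5)
  expect_true(m[["a"]] && m[["b"]])
  expect_false(m[["z"]])
})

test_that("ariScore agrees with the pair-counting oracle on examples", {
  expect_identical(ariScore(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  ## crossed 2x2 partitions: every contingency cell is 1, giving
  ## (0 - 2/3) / (2 - 2/3) = -1/2 (pair-counting oracle and
  ## mclust::adjustedRandIndex agree)
  expect_equal(ariScore(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5,
               tolerance = 1e-12)
  expect_equal(ariPairOracle(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5,
               tolerance = 1e-12)
  ## invariance under relabeling
  expect_equal(ariScore(c(1, 1, 2, 3), c(2, 2, 3, 1)),
               ariScore(c(9, 9, 4, 7), c(1, 1, 2, 3)), tolerance = 1e-12)
})

test_that("ariScore agrees with mclust on random partitions", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    a <- sample(sample(2:5, 1), n, replace = TRUE)
    b <- sample(sample(2:5, 1), n, replace = TRUE)
    expect_equal(ariScore(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ariScore handles degenerate single-class partitions", {
  expect_identical(ariScore(rep(1, 5), rep(2, 5)), 1)  # same set partition
  expect_identical(ariScore(rep(1, 5), c(1, 1, 1, 1, 2)), 0)
})

test_that("nmiScore is 1 for identical partitions and 0 for independence", {
  expect_equal(nmiScore(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1, tolerance = 1e-12)
  expect_equal(nmiScore(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0, tolerance = 1e-12)
  expect_identical(nmiScore(rep(1, 4), rep(1, 4)), 1)
})

test_that("pairwiseAgreement builds a symmetric unit-diagonal matrix", {
  gc <- makeToyCollection(M = 4, seed = 2)
  ag <- pairwiseAgreement(gc$collection)
  v <- agreementValues(ag)
  expect_identical(unname(diag(v)), rep(1, 4))
  expect_lt(max(abs(v - t(v))), 1e-12)
  nmi <- agreementValues(pairwiseAgreement(gc$collection, "NMI"))
  expect_true(all(nmi >= 0 & nmi <= 1 + 1e-12))
})
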