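test_that("kmodes recovers identical base clusterings exactly", {
  gc <- makeToyCollection(M = 5, flipRate = 0, permute = TRUE, seed = 1)
  res <- kmodesConsensus(gc$collection, K = 4, seed = 1)
  expect_identical(ariScore(consensusLabels(res),
                            labelMatrix(gc$collection)[, 1]), 1)
  expect_true(all(diff(objectiveTrace(res)) <= 1e-12))
  expect_identical(objectiveTrace(res)[length(objectiveTrace(res))], 0)
})

test_that("kmodes objective is non-increasing within a run", {
  gc <- makeToyCollection(M = 6, flipRate = 0.2, seed = 2)
  for (s in 1:5) {
    res <- kmodesConsensus(gc$collection, K = 4, nStarts = 1, seed = s)
    expect_true(all(diff(objectiveTrace(res)) <= 1e-12))
  }
})

test_that("kmodes attains the exhaustive optimum on tiny instances", {
  set.seed(30)
  for (rep_i in 1:10) {
    N <- sample(5:8, 1); M <- sample(2:3, 1)
    L <- matrix(sample(3, N * M, replace = TRUE), N, M)
    for (j in seq_len(M)) L[, j] <- as.integer(factor(L[, j]))
    res <- kmodesConsensus(L, K = 2, nStarts = 25, seed = rep_i)
    obj <- objectiveTrace(res)[length(objectiveTrace(res))]
    expect_identical(obj, kmodesOracle(L, 2))
  }
})

test_that("kmodes with K = N reaches objective zero", {
  L <- matrix(c(1:6, c(1, 1, 2, 2, 3, 3)), 6, 2)
  res <- kmodesConsensus(L, K = 6, seed = 1)
  expect_identical(objectiveTrace(res)[length(objectiveTrace(res))], 0)
})

test_that("lca objective trace is non-decreasing", {
  gc <- makeToyCollection(M = 5, flipRate = 0.15, seed = 3)
  for (s in 1:3) {
    fit <- lcaConsensus(gc$collection, K = 4, nStarts = 1, seed = s)
    expect_true(all(diff(objectiveTrace(fit$result)) >= -1e-8))
  }
})

test_that("lca on identical columns is a degenerate mixture", {
  gc <- makeToyCollection(M = 5, flipRate = 0, permute = TRUE, seed = 4)
  fit <- lcaConsensus(gc$collection, K = 4, seed = 1)
  expect_identical(ariScore(fit$result@labels,
                            labelMatrix(gc$collection)[, 1]), 1)
  ## each conditional row concentrates on one observed label
  for (th in fit$model@conditionals)
    expect_true(all(apply(th, 1, max) > 0.99))
})

test_that("lca recovers latent classes under 10% flip noise", {
  ## categorical mixture: truth with K = 3 classes, M = 5 columns each a
  ## 10%-flipped copy, N = 500
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    truth <- sample(3, 500, replace = TRUE)
    L <- vapply(1:5, function(m) {
      x <- truth
      flip <- runif(500) < 0.1
      x[flip] <- 1 + (x[flip] + sample(1:2, sum(flip), TRUE) - 1) %% 3
      as.integer(factor(x))
    }, integer(500))
    fit <- lcaConsensus(L, K = 3, nStarts = 5, seed = seed)
    if (ariScore(fit$result@labels, truth) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("lca warns when K exceeds the distinct row patterns", {
  L <- matrix(rep(c(1L, 2L), each = 4), 8, 2)
  expect_warning(lcaConsensus(L, K = 3, nStarts = 2, seed = 1),
                 "distinct label patterns")
})

test_that("bernoulliJSD matches closed forms and the independent oracle", {
  expect_identical(bernoulliJSD(0.3, 0.3), 0)
  expect_equal(bernoulliJSD(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bernoulliJSD(0.5, 1),
               0.5 * (0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25)) +
                 0.5 * log(1 / 0.75), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    p <- runif(1); q <- runif(1)
    expect_lt(abs(bernoulliJSD(p, q) - jsdOracle(p, q)), 1e-12)
  }
  expect_error(bernoulliJSD(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("weighted consensus fixed point on identical inputs", {
  gc <- makeToyCollection(M = 4, flipRate = 0, permute = TRUE, seed = 5)
  res <- weightedConsensus(gc$collection, K = 4, seed = 1)
  expect_equal(unname(consensusWeights(res)), rep(0.25, 4), tolerance = 1e-9)
  expect_identical(ariScore(res@labels, labelMatrix(gc$collection)[, 1]), 1)
})

test_that("huge lambda forces uniform weights", {
  gc <- makeToyCollection(M = 5, flipRate = 0.25, seed = 6)
  res <- weightedConsensus(gc$collection, lambda = 1e6, K = 4, seed = 1)
  expect_true(all(abs(consensusWeights(res) - 0.2) < 1e-3))
})

test_that("a random column is down-weighted", {
  set.seed(40)
  base <- rep(1:2, each = 10)
  rand <- sample(2, 20, replace = TRUE)
  L <- cbind(base, base, as.integer(factor(rand)))
  res <- weightedConsensus(L, lambda = 0.1, K = 2, seed = 1)
  w <- consensusWeights(res)
  expect_lt(w[3], w[1])
  expect_lt(w[3], w[2])
})

test_that("weighted objective is non-increasing and near the global optimum", {
  ## black-box optimizer oracle on the N = 20, M = 3 instance: optimize
  ## the full regularized objective over (S upper triangle, softmax
  ## weights) and compare objectives
  set.seed(41)
  base <- rep(1:2, each = 10)
  rand <- as.integer(factor(sample(2, 20, replace = TRUE)))
  L <- cbind(base, base, rand)
  lambda <- 0.1
  res <- weightedConsensus(L, lambda = lambda, K = 2, seed = 1)
  trace <- objectiveTrace(res)
  expect_true(all(diff(trace) <= 1e-10))
  altObj <- trace[length(trace)]

  B <- vapply(1:3, function(m) {
    cm <- outer(L[, m], L[, m], "==") * 1
    cm[upper.tri(cm)]
  }, numeric(190))
  objective <- function(par) {
    s <- stats::plogis(par[1:190])
    ew <- exp(par[191:193] - max(par[191:193]))
    w <- ew / sum(ew)
    D <- vapply(1:3, function(m) sum(mapply(jsdOracle, s, B[, m])),
                numeric(1))
    sum(w * D) + lambda * sum(ifelse(w > 0, w * log(w), 0))
  }
  init <- c(stats::qlogis(pmin(pmax(rowMeans(B), 0.02), 0.98)), c(0, 0, 0))
  opt <- stats::optim(init, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_lt(abs(altObj - opt$value), 1e-4)
})

test_that("consensus algorithms are label-permutation equivariant", {
  gc <- makeToyCollection(M = 4, flipRate = 0.1, seed = 7)
  L <- labelMatrix(gc$collection)
  L2 <- L
  K2 <- max(L[, 2])
  L2[, 2] <- (L[, 2] %% K2) + 1L  # cyclic relabeling of one column
  for (alg in c("kmodes", "lca", "weighted")) {
    a <- runConsensus(L, algorithm = alg, K = 4, seed = 3)
    b <- runConsensus(L2, algorithm = alg, K = 4, seed = 3)
    expect_identical(ariScore(a@labels, b@labels), 1,
                     info = paste("algorithm", alg))
  }
})

test_that("single-column consensus returns that clustering", {
  gc <- makeToyCollection(M = 1, flipRate = 0.05, seed = 8)
  L <- labelMatrix(gc$collection)
  K <- max(L[, 1])
  for (alg in c("kmodes", "lca", "weighted")) {
    res <- runConsensus(gc$collection, algorithm = alg, K = K, seed = 2)
    expect_identical(ariScore(res@labels, L[, 1]), 1,
                     info = paste("algorithm", alg))
  }
})

test_that("identical seeds give bit-identical consensus results", {
  gc <- makeToyCollection(M = 5, flipRate = 0.2, seed = 9)
  for (alg in c("kmodes", "lca", "weighted")) {
    a <- runConsensus(gc$collection, algorithm = alg, K = 4, seed = 11)
    b <- runConsensus(gc$collection, algorithm = alg, K = 4, seed = 11)
    expect_identical(consensusLabels(a), consensusLabels(b))
    expect_identical(objectiveTrace(a), objectiveTrace(b))
  }
})

test_that("weighted consensus enforces the dense-storage cap", {
  L <- matrix(1L, 30, 2)
  L[16:30, ] <- 2L
  expect_error(weightedConsensus(L, maxN = 25), "quadratically")
  expect_error(weightedConsensus(L, lambda = 0), "lambda")
})
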