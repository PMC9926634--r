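test_that("additive models get exact per-feature attributions", {
  w <- c(2, -1, 0.5)
  f <- function(X) X %*% w
  X <- rbind(c(1, 1, 1), c(2, 0, -1))
  A1 <- shapleySampling(f, X, nPermutations = 1, seed = 1)
  A2 <- shapleySampling(f, X, nPermutations = 7, seed = 2)
  expected <- sweep(X, 2, w, "*")
  expect_equal(A1, expected, tolerance = 1e-12)  # order is irrelevant
  expect_equal(A2, expected, tolerance = 1e-12)

  fConst <- function(X) rep(3, nrow(X))
  expect_equal(shapleySampling(fConst, X, nPermutations = 5, seed = 1),
               matrix(0, 2, 3), tolerance = 1e-12)
})

test_that("full permutation enumeration recovers exact Shapley values", {
  # interaction model on 3 features
  f <- function(X) X[, 1] * X[, 2] + 2 * X[, 3] + 0.5 * X[, 1] * X[, 3]
  x <- c(1, 2, -1)
  base <- c(0, 0, 0)
  A <- shapleySampling(f, matrix(x, 1), baseline = base,
                       permutations = allPermutations(3))
  phi <- exactShapley(f, x, base)
  expect_equal(as.vector(A), phi, tolerance = 1e-12)

  # efficiency at full enumeration: attributions sum to f(x) - f(baseline)
  f4 <- function(X) X[, 1] * X[, 2] * X[, 3] + X[, 4]^2 - X[, 1]
  x4 <- c(1.5, -1, 2, 0.5)
  A4 <- shapleySampling(f4, matrix(x4, 1), baseline = rep(0, 4),
                        permutations = allPermutations(4))
  expect_equal(sum(A4), f4(matrix(x4, 1)) - f4(matrix(0, 1, 4)),
               tolerance = 1e-12)
  expect_equal(as.vector(A4), exactShapley(f4, x4, rep(0, 4)),
               tolerance = 1e-12)
})

test_that("sampling efficiency error shrinks with more permutations", {
  f <- function(X) X[, 1] * X[, 2] + X[, 3] * X[, 1] - 2 * X[, 2] * X[, 3]
  x <- matrix(c(1, -2, 0.5), 1)
  target <- as.numeric(f(x) - f(matrix(0, 1, 3)))
  A <- shapleySampling(f, x, nPermutations = 10, seed = 4)
  expect_equal(sum(A), target, tolerance = 1e-10)  # holds per permutation
})

test_that("baseline shape mismatches raise shape errors", {
  f <- function(X) rowSums(X)
  expect_error(shapleySampling(f, matrix(0, 1, 3), baseline = c(0, 0)),
               "shape error")
})

test_that("view aggregation normalizes sums to one", {
  A <- matrix(0, 2, 4)
  A[, 1] <- 2; A[, 2] <- 1; A[, 3] <- 1; A[, 4] <- 0
  agg <- aggregateViews(A, c(expression = 1, mutation = 2, cna = 1))
  expect_equal(unname(agg$viewSums), c(0.5, 0.5, 0))
  expect_equal(sum(agg$viewSums), 1)

  # a 10-feature view holding half the attribution has mean 0.05
  B <- cbind(matrix(0.05, 1, 10), matrix(0.5, 1, 1))
  agg2 <- aggregateViews(B, c(a = 10, b = 1))
  expect_equal(unname(agg2$viewMeans[1]), 0.05)

  set.seed(12)
  for (i in 1:100) {
    M <- matrix(rnorm(3 * 12), 3, 12)
    agg3 <- aggregateViews(M, c(x = 5, y = 4, z = 3))
    expect_equal(sum(agg3$viewSums), 1, tolerance = 1e-9)
    expect_true(all(agg3$viewSums >= 0))
    expect_equal(unname(agg3$viewMeans),
                 unname(agg3$viewSums / c(5, 4, 3)), tolerance = 1e-12)
  }

  expect_error(aggregateViews(matrix(0, 2, 3), c(a = 2, b = 1)),
               "normalization error")
  expect_error(aggregateViews(matrix(1, 2, 3), c(a = 2, b = 2)),
               "partition")
})

test_that("signed aggregation is available behind a flag", {
  A <- matrix(c(2, -1, 1), 1)
  agg <- aggregateViews(A, c(a = 2, b = 1), signed = TRUE)
  expect_equal(unname(agg$viewSums), c(0.5, 0.5))
  expect_identical(agg$normalization, "signed")
})

test_that("the view carrying the planted signal dominates attribution", {
  hits <- 0
  for (s in 1:10) {
    spec <- syntheticSpec(nSamples = 60, responderFraction = 0.3,
                          viewDims = c(expression = 12, mutation = 10,
                                       cna = 10),
                          nInformative = c(6, 0, 0), expressionShift = 2.5,
                          binaryRateBase = 0.1, binaryRateShift = 0,
                          seed = s)
    train <- generateMultiOmics(spec, seed = s)
    m <- fitArchitecture(train, "early_integration",
                         quickHP(epochs = 8L, dropout = 0), seed = s)
    target <- subsetSamples(train, 1:20)
    A <- shapleySampling(m, target, nPermutations = 8, seed = s)
    agg <- aggregateViews(A, train)
    if (which.max(agg$viewSums) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
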