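test_that("stratified folds partition samples with balanced classes", {
  expect_error(stratifiedKFold(c(rep(0, 8), rep(1, 2)), k = 5, seed = 1),
               "stratification error")

  # 20 samples, 5 responders, k = 5: exactly 1 responder + 3 others per fold
  y <- c(rep(1, 5), rep(0, 15))
  folds <- stratifiedKFold(y, 5, seed = 2)
  for (f in folds) {
    expect_identical(length(f), 4L)
    expect_equal(sum(y[f]), 1)
  }

  # set algebra over 200 random label vectors
  set.seed(3)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    y <- c(rep(1, k), rep(0, k), rbinom(n - 2 * k, 1, 0.3))
    folds <- stratifiedKFold(y, k, seed = i)
    all_idx <- sort(unlist(folds))
    expect_identical(all_idx, seq_along(y))          # cover, disjoint
    expect_identical(anyDuplicated(unlist(folds)), 0L)
    for (f in folds) {
      for (cls in c(0, 1)) {
        exact <- sum(y == cls) * length(f) / length(y)
        expect_lt(abs(sum(y[f] == cls) - exact), 1 + 1e-9)
      }
    }
  }
})

test_that("hyperparameter draws stay on the grid and are reproducible", {
  grid <- hyperparameterGrid()
  hps <- drawHyperparameters(200, seed = 5)
  expect_identical(length(hps), 200L)
  for (hp in hps) {
    expect_true(hp$batchSize %in% grid$batchSize)
    expect_true(hp$dropout %in% grid$dropout)
    expect_true(hp$epochs %in% grid$epochs)
    expect_true(hp$gamma %in% grid$gamma)
    expect_true(hp$layerDim %in% grid$layerDim)
    expect_true(hp$latentDim %in% grid$layerDim)
    expect_true(hp$learningRate %in% grid$learningRate)
    expect_true(hp$margin %in% grid$margin)
    expect_true(hp$weightDecay %in% grid$weightDecay)
    expect_true(hp$pcaVariance %in% grid$pcaVariance)
    expect_true(hp$lambda %in% grid$gamma)
  }
  expect_identical(drawHyperparameters(50, seed = 9),
                   drawHyperparameters(50, seed = 9))

  # uniformity: batch-size frequencies within 3 sigma of 1/3
  draws <- drawHyperparameters(10000, seed = 11)
  bs <- table(vapply(draws, `[[`, integer(1), "batchSize"))
  expWidth <- 3 * sqrt(10000 * (1 / 3) * (2 / 3))
  for (v in bs) expect_lt(abs(v - 10000 / 3), expWidth)

  expect_error(drawHyperparameters(5, 1, grid = list(batchSize = integer(0))),
               "empty grid dimension")
})

test_that("the pruning bound matches the printed rule and spares the leader", {
  # best mean 0.9; candidate scoring (0.5, 0.4) can reach at most
  # (0.5 + 4)/5 = 0.9 after one fold already -- equality cannot improve,
  # so it is pruned immediately
  tab <- rbind(rep(0.9, 5), c(0.5, 0.4, 1, 1, 1))
  res <- tableSearch(tab, k = 5)
  expect_identical(res$trace$status, c("completed", "pruned"))
  expect_identical(res$bestIndex, 1L)

  # (0.97, 0.4): bound after fold 1 is 0.994 > 0.9 (kept going), after
  # fold 2 it is (1.37 + 3)/5 = 0.874 <= 0.9 -> pruned at two folds
  tab1b <- rbind(rep(0.9, 5), c(0.97, 0.4, 1, 1, 1))
  res1b <- tableSearch(tab1b, k = 5)
  expect_identical(res1b$trace$status[2], "pruned")
  expect_identical(res1b$trace$foldsEvaluated[2], 2L)

  # the first candidate is never pruned
  tab2 <- rbind(c(0.1, 0.1, 0.1, 0.1, 0.1), rep(0.9, 5))
  res2 <- tableSearch(tab2, k = 5)
  expect_identical(res2$trace$status[1], "completed")
  expect_identical(res2$bestIndex, 2L)
})

test_that("pruned search selects the same candidate as exhaustive evaluation", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(runif(12 * 3), 12, 3)
    res <- tableSearch(tab, k = 3, seedFolds = i)
    exhaustiveBest <- max(rowMeans(tab))
    expect_equal(res$bestMean, exhaustiveBest, tolerance = 1e-12)
    # first-seen tie break: earliest candidate attaining the max mean
    expect_identical(res$bestIndex,
                     which(abs(rowMeans(tab) - exhaustiveBest) < 1e-12)[1])
    # soundness: no pruned candidate could have beaten the final best
    pruned <- res$trace$candidate[res$trace$status == "pruned"]
    for (ci in pruned)
      expect_lte(mean(tab[ci, ]), res$bestMean + 1e-12)
  }
})

test_that("nested comparison scores test and external data per outer fold", {
  spec <- syntheticSpec(nSamples = 90, responderFraction = 0.3,
                        viewDims = c(expression = 12, mutation = 10,
                                     cna = 10),
                        nInformative = c(4, 2, 2), seed = 21)
  d <- generateMultiOmics(spec, seed = 21)
  ext <- makeExternalShifted(d, shiftMagnitude = 0.5, seed = 22,
                             nSamples = 40)
  res <- runComparison("early_integration", d, ext, seed = 1,
                       nCandidates = 4, kOuter = 3, kInner = 3)
  expect_identical(nrow(res), 3L * 2L)       # kOuter folds x 2 splits
  expect_identical(sort(unique(res$split)), c("external", "test"))
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  expect_true(all(res$auprc >= 0 & res$auprc <= 1))
  # the same retrained model scores both splits of an outer iteration
  for (of in unique(res$outerFold)) {
    rows <- res[res$outerFold == of, ]
    expect_identical(rows$hyperparameters[1], rows$hyperparameters[2])
  }
  # external data with mismatched features is rejected
  extBad <- generateMultiOmics(syntheticSpec(
    nSamples = 30, responderFraction = 0.3,
    viewDims = c(expression = 13, mutation = 10, cna = 10),
    nInformative = c(2, 2, 2), seed = 5))
  expect_error(runComparison("early_integration", d, extBad, seed = 1,
                             nCandidates = 2, kOuter = 3, kInner = 3),
               "alignment error")
})
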