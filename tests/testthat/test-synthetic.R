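test_that("generation is deterministic and respects the responder count", {
  spec <- tinySpec(seed = 11)
  d1 <- generateMultiOmics(spec)
  d2 <- generateMultiOmics(spec)
  expect_identical(lapply(views(d1), viewMatrix),
                   lapply(views(d2), viewMatrix))
  expect_identical(responseLabels(d1), responseLabels(d2))

  for (frac in c(0.1, 0.25, 0.31)) {
    sp <- syntheticSpec(nSamples = 97, responderFraction = frac,
                        viewDims = c(expression = 5, mutation = 5),
                        nInformative = c(1, 1), seed = 2)
    expect_identical(sum(responseLabels(generateMultiOmics(sp))),
                     as.integer(round(frac * 97)))
  }
})

test_that("generated datasets satisfy the container invariants", {
  d <- generateMultiOmics(tinySpec(seed = 4))
  expect_true(validObject(d))
  expect_true(all(viewMatrix(getView(d, "mutation")) %in% c(0, 1)))
  expect_true(all(viewMatrix(getView(d, "cna")) %in% c(0, 1)))
  expect_identical(unname(viewNames(d)), c("expression", "mutation", "cna"))
})

test_that("impossible rates and counts fail before sampling", {
  expect_error(syntheticSpec(binaryRateBase = 0.9, binaryRateShift = 0.2),
               "rates")
  expect_error(syntheticSpec(nSamples = 30, responderFraction = 0.01),
               "at least 2 responders")
  expect_error(syntheticSpec(viewDims = c(expression = 5),
                             nInformative = 10), "exceed")
})

test_that("a linear baseline separates the planted signal", {
  skip_if_not_installed("glmnet")
  spec <- syntheticSpec(seed = 7)          # reference conditions
  train <- generateMultiOmics(spec, seed = 7)
  test <- generateMultiOmics(spec, seed = 8)
  X <- do.call(cbind, lapply(views(train), viewMatrix))
  Xt <- do.call(cbind, lapply(views(test), viewMatrix))
  fit <- glmnet::glmnet(X, responseLabels(train), family = "binomial",
                        nlambda = 30)
  p <- as.vector(predict(fit, Xt, type = "response",
                         s = min(fit$lambda)))
  expect_gte(auroc(p, responseLabels(test)), 0.85)
})

test_that("null-model data carries no usable signal for a classifier", {
  skip_if_not_installed("glmnet")
  as <- vapply(1:5, function(s) {
    sp <- nullSpec(seed = s, n = 120)
    tr <- generateMultiOmics(sp, seed = s)
    te <- generateMultiOmics(sp, seed = 100 + s)
    X <- do.call(cbind, lapply(views(tr), viewMatrix))
    Xt <- do.call(cbind, lapply(views(te), viewMatrix))
    fit <- glmnet::glmnet(X, responseLabels(tr), family = "binomial",
                          nlambda = 30)
    auroc(as.vector(predict(fit, Xt, type = "response",
                            s = min(fit$lambda))),
          responseLabels(te))
  }, numeric(1))
  expect_gt(mean(as), 0.4)
  expect_lt(mean(as), 0.6)
})

test_that("external shift keeps contracts and degrades a frozen model", {
  spec <- syntheticSpec(nSamples = 200, responderFraction = 0.2,
                        viewDims = c(expression = 60, mutation = 80,
                                     cna = 80),
                        nInformative = c(12, 12, 12), seed = 5)
  train <- generateMultiOmics(spec, seed = 5)

  ext <- makeExternalShifted(train, shiftMagnitude = 2, seed = 99)
  expect_true(all(responseLabels(ext) %in% c(0L, 1L)))
  expect_true(all(viewMatrix(getView(ext, "mutation")) %in% c(0, 1)))
  expect_true(all(viewMatrix(getView(ext, "cna")) %in% c(0, 1)))

  model <- fitArchitecture(train, "early_integration",
                           signalHP(epochs = 15L), seed = 1)
  means <- vapply(c(0, 2, 4), function(s) {
    mean(vapply(1:20, function(r) {
      e <- makeExternalShifted(train, shiftMagnitude = s, seed = 1000 + r)
      auroc(predictResponse(model, e), responseLabels(e))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.005))      # monotone trend of means
  expect_lt(means[3], means[1])               # strictly degraded at the top
})
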