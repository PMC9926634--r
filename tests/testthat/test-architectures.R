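test_that("fit/predict contract holds across architectures", {
  d <- generateMultiOmics(tinySpec(seed = 3))
  hp <- quickHP()
  for (kind in architectureKinds()) {
    m <- fitArchitecture(d, kind, hp, seed = 7)
    p <- predictResponse(m, d)
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(names(p), sampleIDs(d))

    # duplicated samples yield duplicated probabilities
    dd <- subsetSamples(d, c(1:10, 1:10))
    pd <- unname(predictResponse(m, dd))
    expect_equal(pd[1:10], pd[11:20], tolerance = 1e-12)

    # probabilities invariant to sample order
    perm <- sample(seq_along(p))
    pp <- predictResponse(m, subsetSamples(d, perm))
    expect_equal(unname(pp), unname(p[perm]), tolerance = 1e-12)
  }
})

test_that("training is bit-reproducible for fixed seed, hp and data", {
  d <- generateMultiOmics(tinySpec(seed = 5))
  hp <- quickHP(dropout = 0.3)
  for (kind in c("moli", "omics_stacking", "omiembed")) {
    m1 <- fitArchitecture(d, kind, hp, seed = 42)
    m2 <- fitArchitecture(d, kind, hp, seed = 42)
    expect_identical(m1@params, m2@params)
    expect_identical(m1@trainingLog, m2@trainingLog)
  }
})

test_that("single-class data and misused variants are rejected", {
  d <- generateMultiOmics(tinySpec(seed = 2))
  ones <- which(responseLabels(d) == 1)
  expect_error(fitArchitecture(subsetSamples(d, ones), "moli", quickHP(),
                               seed = 1), "stratification error")
  expect_error(fitArchitecture(d, "moli", quickHP(), seed = 1,
                               variant = "complete_integration"),
               "only defined for omics_stacking")
  expect_error(fitArchitecture(d, "pca", quickHP(pcaVariance = 1.2),
                               seed = 1), "pcaVariance")
  expect_error(fitArchitecture(d, "omiembed", quickHP(epochs = 2L),
                               seed = 1), "schedule error")
})

test_that("early integration treats features only through concatenation", {
  # permuting a view's feature order, with the first-layer weight rows
  # permuted to match, leaves every prediction bit-identical: the model is
  # consistent under any order of the concatenated features
  d <- generateMultiOmics(tinySpec(seed = 6))
  m <- fitArchitecture(d, "early_integration", quickHP(), seed = 3)
  p <- ncol(viewMatrix(getView(d, "expression")))
  perm <- sample(p)
  vPerm <- OmicsView("expression",
                     viewMatrix(getView(d, "expression"))[, perm],
                     "continuous")
  dPerm <- MultiOmicsDataset(c(list(vPerm), views(d)[-1]),
                             responseLabels(d))
  m2 <- m
  m2@params$enc$W[seq_len(p), ] <- m@params$enc$W[perm, ]
  m2@meta$featureIDs$expression <- m@meta$featureIDs$expression[perm]
  expect_equal(unname(predictResponse(m2, dPerm)),
               unname(predictResponse(m, d)), tolerance = 1e-12)
})

test_that("PCA integration retains components by explained variance", {
  # rank-1 view: one component at any grid threshold
  set.seed(8)
  n <- 40
  base <- rnorm(n)
  m <- sapply(1:6, function(i) base)          # identical copies
  dimnames(m) <- list(sprintf("s%02d", 1:n), paste0("g", 1:6))
  resp <- setNames(rep(c(0L, 1L), n / 2), rownames(m))
  d1 <- MultiOmicsDataset(OmicsView("expression", m, "continuous"), resp)
  for (thr in c(0.9, 0.95, 0.975, 0.99)) {
    mod <- fitArchitecture(d1, "pca", quickHP(pcaVariance = thr, epochs = 2L),
                           seed = 1)
    expect_identical(ncol(mod@meta$pcas[[1]]$rotation), 1L)
  }

  d <- generateMultiOmics(tinySpec(seed = 12))
  k9 <- fitArchitecture(d, "pca", quickHP(pcaVariance = 0.9, epochs = 2L),
                        seed = 1)
  k99 <- fitArchitecture(d, "pca", quickHP(pcaVariance = 0.99, epochs = 2L),
                         seed = 1)
  for (v in 1:3) {
    kA <- ncol(k9@meta$pcas[[v]]$rotation)
    kB <- ncol(k99@meta$pcas[[v]]$rotation)
    expect_gte(kB, kA)
    # retained components explain at least the configured fraction
    ev <- prcomp(viewMatrix(views(d)[[v]]))$sdev^2
    expect_gte(sum(ev[seq_len(kA)]) / sum(ev), 0.9)
    expect_gte(sum(ev[seq_len(kB)]) / sum(ev), 0.99)
  }
})

test_that("MOLI embeds into the concatenated per-view latent space", {
  d <- generateMultiOmics(tinySpec(seed = 9))
  hp <- quickHP(latentDim = 6L)
  m <- fitArchitecture(d, "moli", hp, seed = 2)
  E <- embedSamples(m, d)
  expect_identical(ncol(E), 3L * 6L)
  expect_identical(rownames(E), sampleIDs(d))
})

test_that("Omics Stacking builds the variant-specific heads", {
  d <- generateMultiOmics(tinySpec(seed = 10))
  hp <- quickHP(epochs = 2L)
  expectHeads <- c(standard = 4L, complete_integration = 7L,
                   without_integration = 3L, without_triplet = 4L)
  for (v in names(expectHeads)) {
    m <- fitArchitecture(d, "omics_stacking", hp, seed = 1, variant = v)
    expect_identical(length(m@meta$headViews), expectHeads[[v]])
    # meta-learner input width equals the number of heads
    expect_identical(nrow(m@params$meta$W), expectHeads[[v]])
    expect_identical(m@variant, v)
  }
})

test_that("Super.FELT phase 2 leaves the phase-1 encoders untouched", {
  d <- generateMultiOmics(tinySpec(seed = 3))
  hp <- stackOmics:::normalizeHP(quickHP(dropout = 0.3, epochs = 4L))
  m <- fitArchitecture(d, "superfelt", hp, seed = 11)
  replay <- stackOmics:::withSeed(11L, stackOmics:::superfeltPhase1(
    stackOmics:::viewMatrices(d), responseLabels(d), hp))
  expect_identical(m@params$enc, replay$enc)
})

test_that("Super.FELT phase-1 best-so-far loss never increases", {
  d <- generateMultiOmics(tinySpec(seed = 4))
  m <- fitArchitecture(d, "superfelt", quickHP(epochs = 6L), seed = 2)
  perView <- split(m@trainingLog$loss[1:18], rep(1:3, each = 6))
  for (lv in perView) {
    best <- cummin(lv)
    expect_true(all(diff(best) <= 0))
  }
})

test_that("OmiEmbed freezes the VAE during phase 2 and splits the schedule", {
  d <- generateMultiOmics(tinySpec(seed = 3))
  hp <- stackOmics:::normalizeHP(quickHP(epochs = 4L))  # phases 2/2/0
  m <- fitArchitecture(d, "omiembed", hp, seed = 12)
  expect_identical(m@meta$phases, c(2L, 2L, 0L))
  replay <- stackOmics:::withSeed(12L, stackOmics:::omiembedPhase1(
    stackOmics:::viewMatrices(d), responseLabels(d),
    stackOmics:::omiembedTargets(d)$targets, hp, 2L))
  vae <- c("encHidden", "mu", "logvar", "decHidden", "dec")
  expect_identical(m@params[vae],
                   stackOmics:::paramValues(replay$params[vae]))

  m7 <- fitArchitecture(d, "omiembed", quickHP(epochs = 7L), seed = 1)
  expect_identical(m7@meta$phases, c(3L, 3L, 1L))
})

test_that("MOMA produces unit-norm modules and row-stochastic attention", {
  d <- generateMultiOmics(tinySpec(seed = 8))
  hp <- stackOmics:::normalizeHP(quickHP(latentDim = 4L, epochs = 3L))
  m <- fitArchitecture(d, "moma", hp, seed = 5)
  K <- m@meta$K
  pl <- stackOmics:::wrapParams(m@params, trainable = FALSE)
  tape <- stackOmics:::adTape()
  hpEval <- hp; hpEval$dropout <- 0
  Xs <- lapply(stackOmics:::viewMatrices(d), stackOmics:::adConst)
  out <- stackOmics:::momaForward(pl, Xs, hpEval, K, tape, train = FALSE)
  for (mod in out$modules) {
    norms <- sqrt(rowSums(mod$val^2))
    expect_true(all(abs(norms - 1) < 1e-5))
  }
  # attention rows (softmax over cosine similarities) sum to one
  A1 <- out$modules[[1]]$val[1:K, ]
  A2 <- out$modules[[2]]$val[1:K, ]
  C <- A1 %*% t(A2)
  S <- exp(C) / rowSums(exp(C))
  expect_true(all(abs(rowSums(S) - 1) < 1e-6))
  # combiner is a fitted logistic regression over the per-view outputs
  expect_identical(length(m@meta$combiner), 4L)
})

test_that("feature mismatches at prediction time are reported by view", {
  d <- generateMultiOmics(tinySpec(seed = 3))
  m <- fitArchitecture(d, "moli", quickHP(epochs = 2L), seed = 1)
  dBad <- generateMultiOmics(syntheticSpec(
    nSamples = 20, responderFraction = 0.3,
    viewDims = c(expression = 9, mutation = 12, cna = 12),
    nInformative = c(2, 2, 2), seed = 1))
  expect_error(predictResponse(m, dBad), "feature mismatch.*expression")
})

test_that("models round-trip through the JSON checkpoint format", {
  d <- generateMultiOmics(tinySpec(seed = 13))
  for (kind in c("moli", "moma", "omiembed", "pca")) {
    m <- fitArchitecture(d, kind, quickHP(epochs = 3L), seed = 4)
    f <- tempfile(fileext = ".json")
    writeModel(m, f)
    m2 <- readModel(f)
    expect_equal(unname(predictResponse(m2, d)),
                 unname(predictResponse(m, d)), tolerance = 1e-12)
  }
})
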