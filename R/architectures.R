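#' Architecture identifiers
#'
#' @return character vector of the seven supported integration
#'   architectures.
#' @export
architectureKinds <- function() {
  c("early_integration", "pca", "moli", "superfelt", "omics_stacking",
    "moma", "omiembed")
}

#' Fit a multi-omics integration architecture
#'
#' Uniform training entry point for the seven architectures. All neural
#' kinds train with minibatch Adagrad (adaptive per-parameter step with L2
#' weight decay) under the given hyperparameter set; training is bit
#' reproducible given `(seed, hp, data)`.
#'
#' Kinds:
#' \describe{
#'   \item{early_integration}{views concatenated into a single input; one
#'     encoding subnetwork plus a classifier layer; binary cross-entropy.}
#'   \item{pca}{per-view PCA retaining components up to cumulative explained
#'     variance `hp$pcaVariance` (labels never touch the projection);
#'     concatenated scores feed a neural classifier.}
#'   \item{moli}{per-view encoders, concatenated latents, one classifier;
#'     BCE plus `gamma` times the triplet loss on the concatenated latents,
#'     trained end to end.}
#'   \item{superfelt}{phase 1 trains each view's encoder alone with triplet
#'     loss on that view's embedding; phase 2 freezes the encoders and
#'     trains a classifier on the concatenated latents.}
#'   \item{omics_stacking}{per-view encoders; one classifier head per view
#'     plus one on the concatenation (variant-dependent), combined by a
#'     single fully connected meta-learner, trained end to end with the
#'     triplet loss on the concatenated embeddings.}
#'   \item{moma}{per-view module encoders emitting unit-norm 2-d module
#'     vectors; pairwise cosine-similarity attention (softmax rows);
#'     per-view logistic outputs trained with cross-entropy; a logistic
#'     regression combiner is fit on the per-view outputs afterwards.}
#'   \item{omiembed}{multi-view variational autoencoder with shared latent
#'     (mu, sigma) and a downstream classifier, trained in three phases
#'     (VAE only; VAE frozen, classifier only; joint fine-tune) with the
#'     total loss `lambda * embed + CE`.}
#' }
#'
#' @param data a [MultiOmicsDataset-class] with both classes present.
#' @param kind one of [architectureKinds()].
#' @param hp hyperparameter set (one element of [drawHyperparameters()], or
#'   a named list with the same fields).
#' @param seed integer seed controlling initialization, batching, dropout
#'   and any sampling.
#' @param variant Omics Stacking variant: `"standard"`,
#'   `"complete_integration"`, `"without_integration"` or
#'   `"without_triplet"`. Only valid for `kind = "omics_stacking"`.
#' @return a [TrainedModel-class].
#' @examples
#' d <- generateMultiOmics(syntheticSpec(nSamples = 60,
#'   viewDims = c(expression = 12, mutation = 10), nInformative = c(3, 3),
#'   responderFraction = 0.3, seed = 2))
#' hp <- list(batchSize = 16L, dropout = 0.1, epochs = 3L, gamma = 0.1,
#'            layerDim = 8L, latentDim = 4L, learningRate = 0.01,
#'            margin = 0.5, weightDecay = 1e-4, pcaVariance = 0.9)
#' m <- fitArchitecture(d, "moli", hp, seed = 1)
#' head(predictResponse(m, d))
#' @export
fitArchitecture <- function(data, kind, hp, seed,
                            variant = c("standard", "complete_integration",
                                        "without_integration",
                                        "without_triplet")) {
  kind <- match.arg(kind, architectureKinds())
  variant <- match.arg(variant)
  if (variant != "standard" && kind != "omics_stacking")
    stop("variants are only defined for omics_stacking, not ", kind)
  hp <- normalizeHP(hp)
  y <- responseLabels(data)
  assertTwoClasses(y)
  seed <- as.integer(seed)
  fitter <- switch(kind,
    early_integration = fitEarlyIntegration,
    pca = fitPCAIntegration,
    moli = fitMOLI,
    superfelt = fitSuperFELT,
    omics_stacking = function(data, hp, seed)
      fitOmicsStacking(data, hp, seed, variant),
    moma = fitMOMA,
    omiembed = fitOmiEmbed)
  model <- withSeed(seed, fitter(data, hp, seed))
  model@meta$featureIDs <- lapply(data@views, function(v) featureIDs(v))
  model@meta$viewDims <- vapply(data@views, function(v) ncol(v@matrix),
                                integer(1))
  model@hp <- hp
  model@seed <- seed
  model@variant <- variant
  validObject(model)
  model
}

newModel <- function(kind, params, meta, log) {
  new("TrainedModel", kind = kind, variant = "standard", hp = list(),
      seed = 0L, params = params, meta = meta,
      trainingLog = data.frame(epoch = seq_along(log), loss = log))
}

## ---- early integration ---------------------------------------------------

eiForward <- function(pl, X, hp, tape, train) {
  h <- adRelu(denseForward(X, pl$enc, tape), tape)
  h <- adDropout(h, hp$dropout, tape, train)
  z <- denseForward(h, pl$cls, tape)
  list(logit = z, embed = h)
}

fitEarlyIntegration <- function(data, hp, seed) {
  X <- do.call(cbind, viewMatrices(data))
  y <- responseLabels(data)
  params <- list(enc = denseParams(ncol(X), hp$layerDim),
                 cls = denseParams(hp$layerDim, 1L))
  log <- runTraining(flattenParams(params), hp, nrow(X), hp$epochs,
    function(b, tape) {
      out <- eiForward(params, adConst(X[b, , drop = FALSE]), hp, tape,
                       train = TRUE)
      adBCELogits(out$logit, yMatrix(y[b]), tape)
    })
  newModel("early_integration", paramValues(params), list(), log)
}

## ---- PCA integration -----------------------------------------------------

fitPCAIntegration <- function(data, hp, seed) {
  y <- responseLabels(data)
  pcas <- lapply(viewMatrices(data), function(m) {
    pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    ev <- pr$sdev^2
    k <- which(cumsum(ev) / sum(ev) >= hp$pcaVariance)[1L]
    list(center = pr$center, rotation = pr$rotation[, seq_len(k),
                                                    drop = FALSE])
  })
  S <- do.call(cbind, mapply(function(m, p)
    sweep(m, 2L, p$center) %*% p$rotation,
    viewMatrices(data), pcas, SIMPLIFY = FALSE))
  params <- list(enc = denseParams(ncol(S), hp$layerDim),
                 cls = denseParams(hp$layerDim, 1L))
  log <- runTraining(flattenParams(params), hp, nrow(S), hp$epochs,
    function(b, tape) {
      out <- eiForward(params, adConst(S[b, , drop = FALSE]), hp, tape,
                       train = TRUE)
      adBCELogits(out$logit, yMatrix(y[b]), tape)
    })
  newModel("pca", paramValues(params), list(pcas = pcas), log)
}

pcaScores <- function(model, data) {
  do.call(cbind, mapply(function(m, p)
    sweep(m, 2L, p$center) %*% p$rotation,
    viewMatrices(data), model@meta$pcas, SIMPLIFY = FALSE))
}

## ---- MOLI ----------------------------------------------------------------

moliForward <- function(pl, Xs, hp, tape, train) {
  lat <- mapply(function(enc, X) encoderForward(enc, X, hp, tape, train),
                pl$enc, Xs, SIMPLIFY = FALSE)
  E <- adCbind(lat, tape)
  z <- denseForward(E, pl$cls, tape)
  list(logit = z, embed = E)
}

fitMOLI <- function(data, hp, seed) {
  Xs <- viewMatrices(data)
  y <- responseLabels(data)
  V <- length(Xs)
  params <- list(
    enc = lapply(Xs, function(m) encoderParams(ncol(m), hp)),
    cls = denseParams(V * hp$latentDim, 1L))
  log <- runTraining(flattenParams(params), hp, length(y), hp$epochs,
    function(b, tape) {
      Xb <- lapply(Xs, function(m) adConst(m[b, , drop = FALSE]))
      out <- moliForward(params, Xb, hp, tape, train = TRUE)
      bce <- adBCELogits(out$logit, yMatrix(y[b]), tape)
      tl <- tripletNode(out$embed, y[b], hp$margin, tape)
      compositeLoss(bce, tl, hp$gamma, tape)
    })
  newModel("moli", paramValues(params), list(), log)
}

## ---- Super.FELT ----------------------------------------------------------

## phase 1: per-view supervised encoders trained with triplet loss alone.
## Kept separate so the freezing contract (phase 2 never touches encoder
## weights) can be checked bit-exactly against a phase-1-only replay.
superfeltPhase1 <- function(Xs, y, hp) {
  enc <- lapply(Xs, function(m) encoderParams(ncol(m), hp))
  log1 <- numeric(0)
  for (v in seq_along(Xs)) {
    lv <- runTraining(flattenParams(enc[[v]]), hp, length(y), hp$epochs,
      function(b, tape) {
        E <- encoderForward(enc[[v]], adConst(Xs[[v]][b, , drop = FALSE]),
                            hp, tape, train = TRUE)
        tl <- tripletNode(E, y[b], hp$margin, tape)
        if (is.null(tl)) adScale(adSum(adMul(E, E, tape), tape), 0, tape)
        else tl
      })
    log1 <- c(log1, lv)
  }
  list(enc = paramValues(enc), log = log1)
}

fitSuperFELT <- function(data, hp, seed) {
  Xs <- viewMatrices(data)
  y <- responseLabels(data)
  V <- length(Xs)
  ph1 <- superfeltPhase1(Xs, y, hp)
  log1 <- ph1$log
  ## phase 2: encoders frozen (dropout off), classifier on concatenated
  ## latents
  encFrozen <- wrapParams(ph1$enc, trainable = FALSE)
  hpEval <- hp; hpEval$dropout <- 0
  L <- do.call(cbind, lapply(seq_len(V), function(v) {
    tape <- adTape()
    encoderForward(encFrozen[[v]], adConst(Xs[[v]]), hpEval, tape,
                   train = FALSE)$val
  }))
  cls <- denseParams(ncol(L), 1L)
  log2 <- runTraining(flattenParams(cls), hp, length(y), hp$epochs,
    function(b, tape) {
      z <- denseForward(adConst(L[b, , drop = FALSE]), cls, tape)
      adBCELogits(z, yMatrix(y[b]), tape)
    })
  newModel("superfelt",
           list(enc = ph1$enc, cls = paramValues(cls)),
           list(), c(log1, log2))
}

superfeltForward <- function(pl, Xs, hp, tape) {
  hpEval <- hp; hpEval$dropout <- 0
  lat <- mapply(function(enc, X)
    encoderForward(enc, X, hpEval, tape, train = FALSE),
    pl$enc, Xs, SIMPLIFY = FALSE)
  E <- adCbind(lat, tape)
  list(logit = denseForward(E, pl$cls, tape), embed = E)
}

## ---- Omics Stacking ------------------------------------------------------

stackingHeads <- function(V, variant) {
  heads <- if (variant == "without_integration") list() else list(seq_len(V))
  heads <- c(lapply(seq_len(V), identity), heads)
  if (variant == "complete_integration" && V >= 2L)
    heads <- c(heads, utils::combn(V, 2L, simplify = FALSE))
  heads
}

stackingForward <- function(pl, Xs, hp, tape, train) {
  lat <- mapply(function(enc, X) encoderForward(enc, X, hp, tape, train),
                pl$enc, Xs, SIMPLIFY = FALSE)
  E <- adCbind(lat, tape)
  probs <- lapply(seq_along(pl$heads), function(i) {
    vs <- pl$headViews[[i]]
    input <- if (length(vs) == 1L) lat[[vs]]
             else adCbind(lat[vs], tape)
    adSigmoid(denseForward(input, pl$heads[[i]], tape), tape)
  })
  meta <- denseForward(adCbind(probs, tape), pl$meta, tape)
  list(logit = meta, embed = E, headProbs = probs)
}

fitOmicsStacking <- function(data, hp, seed, variant) {
  Xs <- viewMatrices(data)
  y <- responseLabels(data)
  V <- length(Xs)
  headViews <- stackingHeads(V, variant)
  params <- list(
    enc = lapply(Xs, function(m) encoderParams(ncol(m), hp)),
    heads = lapply(headViews, function(vs)
      denseParams(length(vs) * hp$latentDim, 1L)),
    meta = denseParams(length(headViews), 1L))
  ## start the meta-learner as a uniform positive average of the heads so
  ## the stack begins at the late-integration consensus instead of a random
  ## (possibly sign-inverted) mixture
  params$meta$W$val <- matrix(1 / length(headViews), length(headViews), 1L)
  params$headViews <- headViews
  gamma <- if (variant == "without_triplet") 0 else hp$gamma
  flat <- flattenParams(params[c("enc", "heads", "meta")])
  log <- runTraining(flat, hp, length(y), hp$epochs,
    function(b, tape) {
      Xb <- lapply(Xs, function(m) adConst(m[b, , drop = FALSE]))
      out <- stackingForward(params, Xb, hp, tape, train = TRUE)
      bce <- adBCELogits(out$logit, yMatrix(y[b]), tape)
      tl <- tripletNode(out$embed, y[b], hp$margin, tape)
      compositeLoss(bce, tl, gamma, tape)
    })
  vals <- paramValues(params[c("enc", "heads", "meta")])
  newModel("omics_stacking", vals, list(headViews = headViews), log)
}

## ---- MOMA ----------------------------------------------------------------

momaForward <- function(pl, Xs, hp, K, tape, train) {
  V <- length(Xs)
  mods <- lapply(seq_len(V), function(v) {
    h <- adRelu(denseForward(Xs[[v]], pl$enc[[v]]$hidden, tape), tape)
    h <- adDropout(h, hp$dropout, tape, train)
    m <- denseForward(h, pl$enc[[v]]$modules, tape)      # n x 2K
    adRowNormalize(adStackModules(m, K, tape), tape)     # (nK) x 2, unit
  })
  attended <- lapply(seq_len(V), function(u) {
    partners <- if (V > 1L) setdiff(seq_len(V), u) else u
    atts <- lapply(partners, function(v)
      adAttention(mods[[u]], mods[[v]], K, tape))
    acc <- atts[[1L]]
    if (length(atts) > 1L)
      for (j in 2L:length(atts)) acc <- adAdd(acc, atts[[j]], tape)
    adScale(acc, 1 / length(atts), tape)
  })
  logits <- lapply(seq_len(V), function(v)
    denseForward(adUnstackModules(attended[[v]], K, tape),
                 pl$head[[v]], tape))
  flats <- lapply(seq_len(V), function(v)
    adUnstackModules(attended[[v]], K, tape))
  list(logits = logits, embed = adCbind(flats, tape), modules = mods)
}

fitMOMA <- function(data, hp, seed) {
  Xs <- viewMatrices(data)
  y <- responseLabels(data)
  V <- length(Xs)
  K <- as.integer(hp$latentDim)       # number of modules, gridded
  if (K < 1L) stop("module count K must be >= 1")
  params <- list(
    enc = lapply(Xs, function(m) list(
      hidden = denseParams(ncol(m), hp$layerDim),
      modules = denseParams(hp$layerDim, 2L * K))),
    head = lapply(seq_len(V), function(v) denseParams(2L * K, 1L)))
  log <- runTraining(flattenParams(params), hp, length(y), hp$epochs,
    function(b, tape) {
      Xb <- lapply(Xs, function(m) adConst(m[b, , drop = FALSE]))
      out <- momaForward(params, Xb, hp, K, tape, train = TRUE)
      yb <- yMatrix(y[b])
      loss <- adBCELogits(out$logits[[1L]], yb, tape)
      if (V > 1L)
        for (v in 2L:V)
          loss <- adAdd(loss, adBCELogits(out$logits[[v]], yb, tape), tape)
      loss
    })
  ## logistic-regression combiner on the omics-specific outputs
  vals <- paramValues(params)
  probs <- momaViewProbs(vals, Xs, hp, K)
  df <- as.data.frame(probs)
  names(df) <- paste0("v", seq_len(V))
  df$y <- y
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  coefs <- stats::coef(fit)
  coefs[is.na(coefs)] <- 0
  newModel("moma", vals, list(K = K, combiner = coefs), log)
}

momaViewProbs <- function(vals, Xs, hp, K) {
  pl <- wrapParams(vals, trainable = FALSE)
  tape <- adTape()
  hpEval <- hp; hpEval$dropout <- 0
  out <- momaForward(pl, lapply(Xs, adConst), hpEval, K, tape,
                     train = FALSE)
  do.call(cbind, lapply(out$logits, function(z) 1 / (1 + exp(-z$val))))
}

## ---- OmiEmbed ------------------------------------------------------------

omiembedEncode <- function(pl, Xs, hp, tape, train) {
  hs <- mapply(function(enc, X) {
    h <- adRelu(denseForward(X, enc, tape), tape)
    adDropout(h, hp$dropout, tape, train)
  }, pl$encHidden, Xs, SIMPLIFY = FALSE)
  H <- adCbind(hs, tape)
  list(mu = denseForward(H, pl$mu, tape),
       logvar = denseForward(H, pl$logvar, tape))
}

omiembedDecode <- function(pl, z, hp, tape, train) {
  h <- adRelu(denseForward(z, pl$decHidden, tape), tape)
  lapply(pl$dec, function(d) denseForward(h, d, tape))   # per-view logits
}

## reconstruction targets: binary views as-is; continuous views min-max
## scaled to [0, 1] (scaling fitted on the training data)
omiembedTargets <- function(data, scale = NULL) {
  ms <- viewMatrices(data)
  enc <- vapply(data@views, function(v) v@encoding, character(1))
  if (is.null(scale)) {
    scale <- lapply(seq_along(ms), function(v) {
      if (enc[v] == "binary") return(NULL)
      lo <- apply(ms[[v]], 2L, min)
      hi <- apply(ms[[v]], 2L, max)
      list(lo = lo, range = pmax(hi - lo, 1e-12))
    })
  }
  targets <- lapply(seq_along(ms), function(v) {
    if (is.null(scale[[v]])) return(ms[[v]])
    t <- sweep(sweep(ms[[v]], 2L, scale[[v]]$lo), 2L, scale[[v]]$range, "/")
    pmin(pmax(t, 0), 1)
  })
  list(targets = targets, scale = scale)
}

omiembedLossNode <- function(pl, Xs, targets, yb, hp, tape, train,
                             part = c("total", "embed", "task")) {
  part <- match.arg(part)
  encoded <- omiembedEncode(pl, Xs, hp, tape, train)
  mu <- encoded$mu; lv <- encoded$logvar
  n <- nrow(mu$val); d <- ncol(mu$val)
  z <- if (train) {
    epsn <- adConst(matrix(stats::rnorm(n * d), n, d))
    adAdd(mu, adMul(adExp(adScale(lv, 0.5, tape), tape), epsn, tape), tape)
  } else mu
  embedNode <- NULL
  if (part != "task") {
    recon <- omiembedDecode(pl, z, hp, tape, train)
    M <- length(Xs)
    bce <- adBCELogits(recon[[1L]], targets[[1L]], tape)
    if (M > 1L)
      for (v in 2L:M)
        bce <- adAdd(bce, adBCELogits(recon[[v]], targets[[v]], tape), tape)
    bce <- adScale(bce, 1 / M, tape)
    klRow <- adRowSums(adAddConst(
      adSub(adAdd(adMul(mu, mu, tape), adExp(lv, tape), tape), lv, tape),
      -1, tape), tape)
    kl <- adScale(adMean(klRow, tape), 0.5, tape)
    embedNode <- adAdd(bce, kl, tape)
    if (part == "embed") return(list(loss = embedNode, mu = mu))
  }
  zc <- denseForward(z, pl$cls, tape)
  task <- adBCELogits(zc, yb, tape)
  loss <- if (part == "task") task
          else adAdd(adScale(embedNode, hp$lambda, tape), task, tape)
  list(loss = loss, mu = mu, logit = zc)
}

## phase 1 of the OmiEmbed schedule: initialize every parameter block and
## train only the VAE. Separate so the phase-2 freezing contract can be
## checked bit-exactly against a phase-1-only replay.
omiembedPhase1 <- function(Xs, y, targets, hp, e1) {
  params <- list(
    encHidden = lapply(Xs, function(m) denseParams(ncol(m), hp$layerDim)),
    mu = denseParams(length(Xs) * hp$layerDim, hp$latentDim),
    logvar = denseParams(length(Xs) * hp$layerDim, hp$latentDim),
    decHidden = denseParams(hp$latentDim, hp$layerDim),
    dec = lapply(Xs, function(m) denseParams(hp$layerDim, ncol(m))),
    cls = denseParams(hp$latentDim, 1L))
  builder <- function(part) function(b, tape) {
    Xb <- lapply(Xs, function(m) adConst(m[b, , drop = FALSE]))
    Tb <- lapply(targets, function(m) m[b, , drop = FALSE])
    omiembedLossNode(params, Xb, Tb, yMatrix(y[b]), hp, tape,
                     train = TRUE, part = part)$loss
  }
  vaeFlat <- flattenParams(params[c("encHidden", "mu", "logvar",
                                    "decHidden", "dec")])
  log1 <- runTraining(vaeFlat, hp, length(y), e1, builder("embed"))
  list(params = params, builder = builder, vaeFlat = vaeFlat, log = log1)
}

fitOmiEmbed <- function(data, hp, seed) {
  if (hp$epochs < 3L)
    stop("schedule error: omiembed needs epochs >= 3 (one per phase)")
  Xs <- viewMatrices(data)
  y <- responseLabels(data)
  tg <- omiembedTargets(data)
  e1 <- as.integer(ceiling(hp$epochs / 3))
  e2 <- as.integer(ceiling(hp$epochs / 3))
  e3 <- hp$epochs - e1 - e2
  ph1 <- omiembedPhase1(Xs, y, tg$targets, hp, e1)
  params <- ph1$params
  builder <- function(part, ...) ph1$builder(part)
  vaeFlat <- ph1$vaeFlat
  clsFlat <- flattenParams(params["cls"])
  log1 <- ph1$log
  log2 <- runTraining(clsFlat, hp, length(y), e2, builder("task"))
  log3 <- if (e3 > 0)
    runTraining(c(vaeFlat, clsFlat), hp, length(y), e3, builder("total"))
  else numeric(0)
  newModel("omiembed", paramValues(params),
           list(scale = tg$scale, phases = c(e1, e2, e3)),
           c(log1, log2, log3))
}

## ---- predict / embed -----------------------------------------------------

forwardModel <- function(object, data) {
  hp <- object@hp
  pl <- wrapParams(object@params, trainable = FALSE)
  Xs <- lapply(viewMatrices(data), adConst)
  tape <- adTape()
  switch(object@kind,
    early_integration = {
      out <- eiForward(pl, adCbind(Xs, tape), hp, tape, train = FALSE)
      list(prob = 1 / (1 + exp(-out$logit$val)), embed = out$embed$val)
    },
    pca = {
      S <- pcaScores(object, data)
      out <- eiForward(pl, adConst(S), hp, tape, train = FALSE)
      list(prob = 1 / (1 + exp(-out$logit$val)), embed = S)
    },
    moli = {
      out <- moliForward(pl, Xs, hp, tape, train = FALSE)
      list(prob = 1 / (1 + exp(-out$logit$val)), embed = out$embed$val)
    },
    superfelt = {
      out <- superfeltForward(pl, Xs, hp, tape)
      list(prob = 1 / (1 + exp(-out$logit$val)), embed = out$embed$val)
    },
    omics_stacking = {
      pl$headViews <- object@meta$headViews
      out <- stackingForward(pl, Xs, hp, tape, train = FALSE)
      list(prob = 1 / (1 + exp(-out$logit$val)), embed = out$embed$val)
    },
    moma = {
      probs <- momaViewProbs(object@params,
                             viewMatrices(data), hp, object@meta$K)
      cf <- object@meta$combiner
      eta <- cf[1L] + probs %*% cf[-1L]
      tapeE <- adTape()
      hpEval <- hp; hpEval$dropout <- 0
      out <- momaForward(pl, Xs, hpEval, object@meta$K, tapeE,
                         train = FALSE)
      list(prob = as.vector(1 / (1 + exp(-eta))), embed = out$embed$val)
    },
    omiembed = {
      tg <- omiembedTargets(data, object@meta$scale)
      res <- omiembedLossNode(pl, Xs, tg$targets,
                              yMatrix(responseLabels(data)), hp, tape,
                              train = FALSE, part = "total")
      list(prob = 1 / (1 + exp(-res$logit$val)), embed = res$mu$val)
    },
    stop("unknown kind ", object@kind))
}

#' @rdname predictResponse
#' @export
setMethod("predictResponse", "TrainedModel", function(object, data) {
  checkFeatureMatch(object, data)
  p <- as.vector(forwardModel(object, data)$prob)
  names(p) <- sampleIDs(data)
  p
})

#' @rdname embedSamples
#' @export
setMethod("embedSamples", "TrainedModel", function(object, data) {
  checkFeatureMatch(object, data)
  E <- forwardModel(object, data)$embed
  rownames(E) <- sampleIDs(data)
  E
})
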