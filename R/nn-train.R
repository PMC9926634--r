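## Shared training machinery for the neural architectures: parameter-tree
## flattening, the minibatch Adagrad loop, and graph fragments reused by
## several architectures (encoders, triplet-loss node, BCE node).

flattenParams <- function(x) {
  if (is.environment(x)) return(list(x))
  unlist(lapply(x, flattenParams), recursive = FALSE, use.names = FALSE)
}

paramValues <- function(x) {
  if (is.environment(x)) return(x$val)
  lapply(x, paramValues)
}

wrapParams <- function(x, trainable = FALSE) {
  if (is.matrix(x)) return(if (trainable) adParam(x) else adConst(x))
  lapply(x, wrapParams, trainable = trainable)
}

## minibatch loop; lossBuilder(batchIdx, tape) -> loss node.
## Optimizes only trainParams (a flat list of nodes); any other parameter
## referenced by the graph stays frozen.
runTraining <- function(trainParams, hp, n, epochs, lossBuilder) {
  state <- adagradInit(trainParams)
  log <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / hp$batchSize)
    tot <- 0
    for (bi in seq_len(nb)) {
      b <- ord[((bi - 1L) * hp$batchSize + 1L):min(bi * hp$batchSize, n)]
      tape <- adTape()
      zeroGrads(trainParams)
      loss <- lossBuilder(b, tape)
      adBackward(tape, loss)
      state <- adagradStep(trainParams, state, hp$learningRate,
                           hp$weightDecay)
      tot <- tot + loss$val[1]
    }
    log[e] <- tot / nb
  }
  log
}

## one-hidden-layer view encoder: dense -> relu -> dropout -> dense -> relu
encoderParams <- function(p, hp) {
  list(hidden = denseParams(p, hp$layerDim),
       latent = denseParams(hp$layerDim, hp$latentDim))
}

encoderForward <- function(pl, X, hp, tape, train) {
  h <- adRelu(denseForward(X, pl$hidden, tape), tape)
  h <- adDropout(h, hp$dropout, tape, train)
  adRelu(denseForward(h, pl$latent, tape), tape)
}

## triplet-loss node on an embedding node; NULL when no triplet exists
tripletNode <- function(E, labels, margin, tape) {
  tri <- mineAllTriplets(labels, warn = FALSE)
  if (nrow(tri) == 0L) return(NULL)
  a <- adRows(E, tri[, 1L], tape)
  p <- adRows(E, tri[, 2L], tape)
  nn <- adRows(E, tri[, 3L], tape)
  dap <- adSub(a, p, tape)
  dan <- adSub(a, nn, tape)
  sap <- adRowSums(adMul(dap, dap, tape), tape)
  san <- adRowSums(adMul(dan, dan, tape), tape)
  adSum(adRelu(adAddConst(adSub(sap, san, tape), margin, tape), tape), tape)
}

## classification + gamma * triplet composite (triplet may be NULL)
compositeLoss <- function(bce, triplet, gamma, tape) {
  if (is.null(triplet) || gamma == 0) return(bce)
  adAdd(bce, adScale(triplet, gamma, tape), tape)
}

yMatrix <- function(labels) matrix(as.numeric(labels), ncol = 1L)

viewMatrices <- function(data) lapply(data@views, function(v) v@matrix)

## shape guard used by predict/embed
checkFeatureMatch <- function(object, data) {
  expected <- object@meta$featureIDs
  vn <- unname(viewNames(data))
  if (!identical(vn, names(expected)))
    stop("view mismatch: model expects views [",
         paste(names(expected), collapse = ", "), "], data has [",
         paste(vn, collapse = ", "), "]")
  for (nm in names(expected)) {
    got <- featureIDs(getView(data, nm))
    if (!identical(got, expected[[nm]]))
      stop("feature mismatch in view '", nm, "': expected ",
           length(expected[[nm]]), " features, got ", length(got))
  }
  invisible(TRUE)
}

assertTwoClasses <- function(labels) {
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("stratification error: training data needs >= 2 samples per class")
  invisible(TRUE)
}
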