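# Shared fixtures and independent oracles used across test files.

# small three-view planted-signal spec (fast fits)
tinySpec <- function(seed = 3, n = 80) {
  syntheticSpec(nSamples = n, responderFraction = 0.3,
                viewDims = c(expression = 15, mutation = 12, cna = 12),
                nInformative = c(4, 2, 2), expressionShift = 1.5,
                binaryRateBase = 0.1, binaryRateShift = 0.25, seed = seed)
}

# no planted signal at all
nullSpec <- function(seed = 1, n = 80) {
  syntheticSpec(nSamples = n, responderFraction = 0.3,
                viewDims = c(expression = 20, mutation = 30, cna = 30),
                nInformative = c(0, 0, 0), expressionShift = 0,
                binaryRateBase = 0.1, binaryRateShift = 0, seed = seed)
}

quickHP <- function(...) {
  hp <- list(batchSize = 16L, dropout = 0.1, epochs = 5L, gamma = 0.1,
             layerDim = 16L, latentDim = 8L, learningRate = 0.01,
             margin = 0.5, weightDecay = 1e-4, pcaVariance = 0.95)
  utils::modifyList(hp, list(...))
}

# well-performing grid-valid set used for planted-signal regression bounds
signalHP <- function(...) {
  hp <- list(batchSize = 16L, dropout = 0.1, epochs = 20L, gamma = 0.3,
             layerDim = 64L, latentDim = 32L, learningRate = 0.01,
             margin = 0.5, weightDecay = 1e-4, pcaVariance = 0.95)
  utils::modifyList(hp, list(...))
}

# brute-force triple-loop triplet enumeration (independent of the package)
bruteTriplets <- function(labels) {
  n <- length(labels)
  out <- NULL
  for (a in seq_len(n)) for (p in seq_len(n)) for (g in seq_len(n)) {
    if (a != p && labels[a] == labels[p] && labels[g] != labels[a])
      out <- rbind(out, c(a, p, g))
  }
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

# brute-force triplet loss (independent triple loop over a triplet matrix)
bruteTripletLoss <- function(E, labels, margin) {
  tri <- bruteTriplets(labels)
  tot <- 0
  if (nrow(tri) == 0) return(0)
  for (r in seq_len(nrow(tri))) {
    dap <- sum((E[tri[r, 1], ] - E[tri[r, 2], ])^2)
    dan <- sum((E[tri[r, 1], ] - E[tri[r, 3], ])^2)
    tot <- tot + max(dap - dan + margin, 0)
  }
  tot
}

# pairwise-comparison AUROC oracle
pairwiseAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact 2^n sign-assignment enumeration for the signed-rank test
enumWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  pLe <- mean(ws <= wObs + 1e-9)
  pGe <- mean(ws >= wObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# exact Shapley values by coalition enumeration (<= ~10 features)
exactShapley <- function(f, x, baseline) {
  p <- length(x)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  vals <- apply(subsets, 1, function(s) {
    z <- baseline
    z[as.logical(s)] <- x[as.logical(s)]
    f(matrix(z, 1))
  })
  key <- function(s) sum(2^(which(s) - 1)) + 1
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (r in 0:(p - 1)) {
      if (r == 0) combos <- list(integer(0))
      else combos <- utils::combn(others, r, simplify = FALSE)
      w <- factorial(r) * factorial(p - r - 1) / factorial(p)
      for (S in combos) {
        sv <- logical(p); sv[S] <- TRUE
        swi <- sv; swi[i] <- TRUE
        phi[i] <- phi[i] + w * (vals[key(swi)] - vals[key(sv)])
      }
    }
  }
  phi
}

# run the hyperparameter search against a synthetic score table: scoreFun
# looks up the AUROC a candidate would reach on a given fold
tableSearch <- function(tab, k = ncol(tab), seedFolds = 1) {
  nCand <- nrow(tab)
  n <- 6 * k
  d <- generateMultiOmics(syntheticSpec(
    nSamples = n, responderFraction = 0.5,
    viewDims = c(expression = 4, mutation = 4), nInformative = c(1, 1),
    seed = 1))
  folds <- stratifiedKFold(responseLabels(d), k, seed = seedFolds)
  foldOf <- function(valIdx)
    which(vapply(folds, function(f) setequal(f, valIdx), logical(1)))
  candidates <- lapply(seq_len(nCand), function(i) list(id = i))
  innerCVSearch("moli", candidates, d, folds,
                scoreFun = function(hp, tr, va) tab[hp$id, foldOf(va)])
}

allPermutations <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (i in seq_len(p)) {
    rest <- allPermutations(p - 1)
    out <- c(out, lapply(rest, function(r) c(i, setdiff(seq_len(p), i)[r])))
  }
  out
}
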