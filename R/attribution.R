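## View-level attribution by Shapley value sampling: features are added one
## by one to a baseline in random order; a feature's attribution is the
## mean, over orders, of the model-output change when it flips from its
## baseline value to its actual value given the features already added.

#' Shapley value sampling attributions
#'
#' Monte-Carlo estimate of per-feature Shapley values for an arbitrary
#' prediction function. For each sampled permutation, features are added
#' one at a time to the baseline and the change in model output is credited
#' to the feature just added; attributions average over permutations. With
#' `permutations` set to all `p!` orders the estimate is the exact Shapley
#' value.
#'
#' @param model a [TrainedModel-class], or a plain `function(X)` mapping a
#'   samples x features matrix to a numeric output per sample.
#' @param samples samples x features matrix to attribute (for a
#'   `TrainedModel`, pass a [MultiOmicsDataset-class] instead).
#' @param baseline numeric vector shaped like one sample; defaults to
#'   all zeros (the reference state of binary views; continuous views are
#'   standardized, so zero is the mean profile).
#' @param nPermutations number of random feature orders (default 50).
#' @param seed integer seed for the permutation draws.
#' @param permutations optional explicit list of feature orders, overriding
#'   the random draws (used for exact enumeration on small p).
#' @return samples x features attribution matrix.
#' @examples
#' f <- function(X) X %*% c(2, -1, 0.5)
#' A <- shapleySampling(f, matrix(1, 1, 3), nPermutations = 5, seed = 1)
#' A  # additive model: attribution of feature i is exactly w_i * x_i
#' @export
shapleySampling <- function(model, samples, baseline = NULL,
                            nPermutations = 50L, seed = 1L,
                            permutations = NULL) {
  if (is(model, "TrainedModel")) {
    if (!is(samples, "MultiOmicsDataset"))
      stop("pass a MultiOmicsDataset when attributing a TrainedModel")
    return(shapleyForModel(model, samples, baseline, nPermutations, seed,
                           permutations))
  }
  f <- model
  X <- as.matrix(samples)
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(baseline)) baseline <- numeric(p)
  if (length(baseline) != p)
    stop("shape error: baseline has length ", length(baseline),
         ", samples have ", p, " features")
  if (is.null(permutations)) {
    stopifnot(nPermutations >= 1L)
    permutations <- withSeed(seed, lapply(seq_len(nPermutations),
                                          function(i) sample.int(p)))
  }
  A <- matrix(0, n, p, dimnames = dimnames(X))
  B <- matrix(baseline, n, p, byrow = TRUE)
  for (ord in permutations) {
    Z <- B
    prev <- as.numeric(f(Z))
    for (j in ord) {
      Z[, j] <- X[, j]
      cur <- as.numeric(f(Z))
      A[, j] <- A[, j] + (cur - prev)
      prev <- cur
    }
  }
  A / length(permutations)
}

shapleyForModel <- function(model, data, baseline, nPermutations, seed,
                            permutations) {
  dims <- model@meta$viewDims
  vn <- names(dims)
  enc <- vapply(data@views, function(v) v@encoding, character(1))
  ids <- sampleIDs(data)
  fids <- model@meta$featureIDs
  f <- function(X) {
    ends <- cumsum(dims)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    views <- lapply(seq_along(dims), function(v) {
      m <- X[, starts[v]:ends[v], drop = FALSE]
      dimnames(m) <- list(ids, fids[[v]])
      OmicsView(vn[v], m, enc[v])
    })
    d <- MultiOmicsDataset(views, responseLabels(data))
    unname(predictResponse(model, d))
  }
  X <- do.call(cbind, viewMatrices(data))
  shapleySampling(f, X, baseline, nPermutations, seed, permutations)
}

#' Aggregate feature attributions to the view level
#'
#' Normalizes the total attribution to one and reports, per view, the
#' summed attribution (the view's influence on the prediction) and the
#' mean attribution per feature (the average influence of one of its
#' features). Normalization divides by the total of absolute attributions,
#' so the reported view shares are non-negative and sum to one.
#'
#' @param attributions samples x features matrix from [shapleySampling()].
#' @param viewDims named per-view feature counts partitioning the columns
#'   (for a model, `model@meta$viewDims`); alternatively a
#'   [MultiOmicsDataset-class] from which the partition is read.
#' @param signed keep signed attributions (sums may then be negative and
#'   are normalized by the signed total).
#' @return list with `viewSums` (normalized, total 1), `viewMeans`
#'   (`viewSums / featureCount`), `featureCounts`, and the
#'   `normalization` used.
#' @export
aggregateViews <- function(attributions, viewDims, signed = FALSE) {
  if (is(viewDims, "MultiOmicsDataset"))
    viewDims <- vapply(viewDims@views, function(v) ncol(v@matrix),
                       integer(1))
  if (sum(viewDims) != ncol(attributions))
    stop("view boundaries (", sum(viewDims),
         ") do not partition the feature axis (", ncol(attributions), ")")
  perFeature <- colMeans(attributions)       # mean over samples
  vals <- if (signed) perFeature else abs(perFeature)
  total <- sum(if (signed) perFeature else abs(perFeature))
  if (total == 0) stop("normalization error: total attribution is zero")
  ends <- cumsum(viewDims)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  viewSums <- vapply(seq_along(viewDims), function(v)
    sum(vals[starts[v]:ends[v]]) / total, numeric(1))
  names(viewSums) <- names(viewDims)
  list(viewSums = viewSums,
       viewMeans = viewSums / as.numeric(viewDims),
       featureCounts = viewDims,
       normalization = if (signed) "signed" else "absolute")
}
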