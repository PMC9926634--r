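## The fair-comparison engine: stratified nested cross-validation, random
## hyperparameter search with the upper-bound pruning rule, retraining on
## train + validation, and scoring on the test fold and an untouched
## external set.

#' Stratified k-fold assignment
#'
#' Splits indices into `k` disjoint folds covering all samples, with each
#' class dealt round-robin after a seeded shuffle, so per-fold class counts
#' deviate from exact proportionality by less than one sample.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors.
#' @export
stratifiedKFold <- function(labels, k, seed) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (min(counts) < k)
    stop("stratification error: minority class has ", min(counts),
         " samples, fewer than k = ", k)
  withSeed(seed, {
    folds <- vector("list", k)
    offset <- 0L
    for (cls in c(1, 0)) {
      idx <- sample(which(labels == cls))
      asg <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[asg == f])
      offset <- (offset + length(idx)) %% k
    }
    lapply(folds, sort)
  })
}

#' Inner cross-validation with upper-bound pruning
#'
#' Evaluates hyperparameter candidates in order over the inner folds.
#' After `j` of `k` folds with validation AUROCs `a_1..a_j`, the best mean
#' a candidate can still reach is `(sum(a) + (k - j)) / k` (AUROC 1 on all
#' remaining folds); when that bound is `<=` the best completed mean so
#' far, the candidate is pruned and the search moves on. The first
#' candidate attaining the maximal completed mean wins ties.
#'
#' @param kind architecture kind (see [architectureKinds()]).
#' @param candidates list of hyperparameter sets.
#' @param data training [MultiOmicsDataset-class].
#' @param innerFolds list of validation index sets partitioning
#'   `seq_len(nSamples(data))` (from [stratifiedKFold()]).
#' @param seed seed forwarded to each training run.
#' @param variant passed to [fitArchitecture()].
#' @param scoreFun optional `function(hp, trainIdx, valIdx)` returning a
#'   validation AUROC; defaults to fitting `kind` and scoring with
#'   [auroc()]. Exposed so the pruning rule can be audited on synthetic
#'   score tables.
#' @return list with `best` (the selected set), `bestMean`, and `trace`
#'   (a data.frame: candidate, folds evaluated, mean when completed,
#'   status `completed`/`pruned`, and the running best).
#' @export
innerCVSearch <- function(kind, candidates, data, innerFolds, seed = 1L,
                          variant = "standard", scoreFun = NULL) {
  k <- length(innerFolds)
  y <- responseLabels(data)
  if (is.null(scoreFun))
    scoreFun <- function(hp, trainIdx, valIdx) {
      model <- fitArchitecture(subsetSamples(data, trainIdx), kind, hp,
                               seed = seed, variant = variant)
      p <- predictResponse(model, subsetSamples(data, valIdx))
      auroc(p, y[valIdx])
    }
  bestMean <- -Inf
  bestIdx <- NA_integer_
  trace <- data.frame(candidate = seq_along(candidates),
                      foldsEvaluated = 0L, mean = NA_real_,
                      status = NA_character_, bestSoFar = NA_real_)
  errors <- character(length(candidates))
  for (ci in seq_along(candidates)) {
    scores <- numeric(0)
    status <- "completed"
    for (fi in seq_len(k)) {
      valIdx <- innerFolds[[fi]]
      trainIdx <- setdiff(unlist(innerFolds), valIdx)
      s <- tryCatch(scoreFun(candidates[[ci]], trainIdx, valIdx),
                    error = function(e) e)
      if (inherits(s, "error")) {
        errors[ci] <- conditionMessage(s)
        status <- "failed"
        break
      }
      scores <- c(scores, s)
      bound <- (sum(scores) + (k - fi) * 1.0) / k
      if (fi < k && bound <= bestMean) {
        status <- "pruned"
        break
      }
    }
    cmean <- if (status == "completed") mean(scores) else NA_real_
    if (status == "completed" && cmean > bestMean) {
      bestMean <- cmean
      bestIdx <- ci
    }
    trace$foldsEvaluated[ci] <- length(scores)
    trace$mean[ci] <- cmean
    trace$status[ci] <- status
    trace$bestSoFar[ci] <- if (is.finite(bestMean)) bestMean else NA_real_
  }
  if (is.na(bestIdx))
    stop("search failure: no candidate completed; diagnostics: ",
         paste(unique(errors[nzchar(errors)]), collapse = " | "))
  list(best = candidates[[bestIdx]], bestIndex = bestIdx,
       bestMean = bestMean, trace = trace)
}

#' Run the full architecture comparison
#'
#' For each architecture and each outer fold of a stratified
#' `kOuter x kInner` nested cross-validation: draw `nCandidates` fresh
#' hyperparameter sets (seeded per fold), select the best by mean inner
#' validation AUROC under the pruning rule, retrain on the combined outer
#' training data (train + validation), and score the outer test fold and
#' the untouched external set with AUROC and AUPRC — both from the same
#' retrained model. The external data never participates in search or
#' retraining.
#'
#' @param kinds character vector of architecture kinds (and/or Omics
#'   Stacking variants written `"omics_stacking:variant"`).
#' @param data training [MultiOmicsDataset-class].
#' @param externalData external-test [MultiOmicsDataset-class] with the
#'   same views/features.
#' @param seed master seed; per-fold candidate draws use `seed + fold`.
#' @param nCandidates hyperparameter sets drawn per outer fold (200 in the
#'   full protocol; reduce for quick runs).
#' @param kOuter,kInner fold counts (5 x 5 in the full protocol).
#' @param grid hyperparameter grid for [drawHyperparameters()].
#' @return data.frame with columns architecture, outerFold, split
#'   (`test`/`external`), auroc, auprc, hyperparameters (JSON string).
#' @export
runComparison <- function(kinds, data, externalData, seed = 1L,
                          nCandidates = 200L, kOuter = 5L, kInner = 5L,
                          grid = hyperparameterGrid()) {
  y <- responseLabels(data)
  for (v in viewNames(data))
    if (!identical(featureIDs(getView(data, v)),
                   featureIDs(getView(externalData, v))))
      stop("alignment error: external data features differ in view '", v, "'")
  outerFolds <- stratifiedKFold(y, kOuter, seed)
  allIdx <- seq_along(y)
  res <- list()
  for (kindSpec in kinds) {
    parts <- strsplit(kindSpec, ":", fixed = TRUE)[[1L]]
    kind <- parts[1L]
    variant <- if (length(parts) > 1L) parts[2L] else "standard"
    for (of in seq_len(kOuter)) {
      testIdx <- outerFolds[[of]]
      trainIdx <- setdiff(allIdx, testIdx)
      stopifnot(length(intersect(testIdx, trainIdx)) == 0L)  # leakage audit
      trainData <- subsetSamples(data, trainIdx)
      innerFolds <- stratifiedKFold(y[trainIdx], kInner, seed + of)
      candidates <- drawHyperparameters(nCandidates, seed = seed + of,
                                        grid = grid)
      sel <- innerCVSearch(kind, candidates, trainData, innerFolds,
                           seed = seed, variant = variant)
      model <- fitArchitecture(trainData, kind, sel$best, seed = seed,
                               variant = variant)
      pTest <- predictResponse(model, subsetSamples(data, testIdx))
      pExt <- predictResponse(model, externalData)
      res[[length(res) + 1L]] <- data.frame(
        architecture = kindSpec,
        outerFold = rep(of, 2L),
        split = c("test", "external"),
        auroc = c(auroc(pTest, y[testIdx]),
                  auroc(pExt, responseLabels(externalData))),
        auprc = c(auprc(pTest, y[testIdx]),
                  auprc(pExt, responseLabels(externalData))),
        hyperparameters = rep(as.character(
          jsonlite::toJSON(sel$best, auto_unbox = TRUE)), 2L))
    }
  }
  do.call(rbind, res)
}
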