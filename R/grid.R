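#' The hyperparameter search grid
#'
#' The fixed value grid every architecture draws from during random search:
#' batch size, dropout rate, epochs, triplet weight gamma, layer dimension
#' (drawn independently for the encoder and latent widths), learning rate,
#' triplet margin, weight decay and the PCA explained-variance threshold.
#' The variational balancing weight `lambda` is drawn from the same value
#' set as `gamma` (both are loss-balancing weights).
#'
#' @return named list of value vectors.
#' @export
hyperparameterGrid <- function() {
  list(
    batchSize = c(8L, 16L, 32L),
    dropout = c(0.1, 0.3, 0.5, 0.7),
    epochs = 2:20,
    gamma = c(0.0, 0.1, 0.3, 0.5),
    layerDim = c(32L, 64L, 128L, 256L, 512L, 1024L),
    learningRate = c(0.001, 0.01),
    margin = c(0.2, 0.5, 1),
    weightDecay = c(0.0001, 0.001, 0.01, 0.05, 0.1),
    pcaVariance = c(0.9, 0.95, 0.975, 0.99)
  )
}

#' Draw random hyperparameter sets from the grid
#'
#' Independent uniform draws (with replacement across sets) from each grid
#' dimension. `layerDim` is drawn twice, independently, for the encoder
#' hidden width (`layerDim`) and the latent width (`latentDim`); `lambda`
#' is drawn from the `gamma` values.
#'
#' @param n number of sets.
#' @param seed integer seed; same seed, same draw sequence.
#' @param grid grid as returned by [hyperparameterGrid()].
#' @return list of `n` named hyperparameter lists.
#' @examples
#' hps <- drawHyperparameters(3, seed = 1)
#' hps[[1]]$batchSize
#' @export
drawHyperparameters <- function(n, seed, grid = hyperparameterGrid()) {
  for (nm in names(grid))
    if (length(grid[[nm]]) < 1L) stop("empty grid dimension: ", nm)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      hp <- lapply(grid, function(v) v[sample.int(length(v), 1L)])
      hp$latentDim <- grid$layerDim[sample.int(length(grid$layerDim), 1L)]
      hp$lambda <- grid$gamma[sample.int(length(grid$gamma), 1L)]
      hp
    })
  })
}

## Validate an hp list against the grid; fill derived fields if absent.
normalizeHP <- function(hp, grid = hyperparameterGrid()) {
  needed <- c("batchSize", "dropout", "epochs", "gamma", "layerDim",
              "learningRate", "margin", "weightDecay", "pcaVariance")
  miss <- setdiff(needed, names(hp))
  if (length(miss)) stop("missing hyperparameters: ",
                         paste(miss, collapse = ", "))
  if (is.null(hp$latentDim)) hp$latentDim <- hp$layerDim
  if (is.null(hp$lambda)) hp$lambda <- hp$gamma
  if (hp$pcaVariance <= 0 || hp$pcaVariance > 1)
    stop("pcaVariance must lie in (0, 1]")
  hp
}
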