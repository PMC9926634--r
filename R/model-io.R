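#' Save / load a trained model as a single JSON file
#'
#' Checkpoints are plain JSON holding the architecture spec (kind, variant,
#' hyperparameters, seed) together with every parameter matrix and the
#' bookkeeping needed for prediction, so a model round-trips through text.
#'
#' @param model a [TrainedModel-class].
#' @param path output file.
#' @return `path`, invisibly (`writeModel`); the restored
#'   [TrainedModel-class] (`readModel`).
#' @export
writeModel <- function(model, path) {
  meta <- model@meta
  # named atomic vectors lose their names in JSON arrays; keep them as
  # objects
  meta$viewDims <- as.list(meta$viewDims)
  payload <- list(
    format = "stackOmics-model-1",
    kind = model@kind,
    variant = model@variant,
    hp = model@hp,
    seed = model@seed,
    params = model@params,
    meta = meta,
    trainingLog = model@trainingLog)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

restoreMatrices <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, restoreMatrices))
  if (is.numeric(x) && is.null(dim(x))) return(matrix(x, nrow = 1L))
  if (is.numeric(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    return(x)
  }
  x
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "stackOmics-model-1"))
    stop("not a stackOmics model checkpoint: ", path)
  meta <- payload$meta
  meta$viewDims <- unlist(meta$viewDims)
  storage.mode(meta$viewDims) <- "integer"
  if (!is.null(meta$combiner)) meta$combiner <- unlist(meta$combiner)
  if (!is.null(meta$pcas))
    meta$pcas <- lapply(meta$pcas, function(p)
      list(center = unlist(p$center), rotation = restoreMatrices(p$rotation)))
  if (!is.null(meta$scale))
    meta$scale <- lapply(meta$scale, function(s)
      if (is.null(s) || length(s) == 0L) NULL
      else list(lo = unlist(s$lo), range = unlist(s$range)))
  if (!is.null(meta$headViews))
    meta$headViews <- lapply(meta$headViews, as.integer)
  new("TrainedModel",
      kind = payload$kind,
      variant = payload$variant,
      hp = payload$hp,
      seed = as.integer(payload$seed),
      params = restoreMatrices(payload$params),
      meta = meta,
      trainingLog = as.data.frame(payload$trainingLog))
}
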