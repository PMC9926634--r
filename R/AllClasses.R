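#' @import methods
NULL

#' OmicsView: one measurement modality over shared samples
#'
#' An `OmicsView` holds a single omics modality as a samples x features
#' numeric matrix, together with its feature (gene) identifiers and a value
#' encoding. Continuous views carry real-valued measurements (e.g.
#' standardized gene expression); binary views carry 0/1 indicators (e.g.
#' somatic mutation status, binarized copy-number aberration).
#'
#' @slot name single character, the view identifier (e.g. `"expression"`).
#' @slot matrix numeric matrix, samples in rows, features in columns;
#'   rownames are sample IDs, colnames are feature IDs.
#' @slot encoding `"continuous"` or `"binary"`; binary views must contain
#'   only 0 and 1.
#'
#' @seealso [OmicsView()] for the constructor, [varianceFilter()],
#'   [MultiOmicsDataset-class].
#' @export
setClass("OmicsView",
  representation(
    name = "character",
    matrix = "matrix",
    encoding = "character"
  )
)

setValidity("OmicsView", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!is.numeric(object@matrix))
    msg <- c(msg, "'matrix' must be numeric")
  if (!length(object@encoding) == 1L ||
      !object@encoding %in% c("continuous", "binary"))
    msg <- c(msg, "'encoding' must be \"continuous\" or \"binary\"")
  fid <- colnames(object@matrix)
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature IDs (colnames) must be present and unique")
  if (is.null(rownames(object@matrix)))
    msg <- c(msg, "sample IDs (rownames) must be present")
  if (identical(object@encoding, "binary") &&
      !all(object@matrix %in% c(0, 1)))
    msg <- c(msg, sprintf("binary view '%s' contains values outside {0, 1}",
                          object@name))
  if (length(msg)) msg else TRUE
})

#' MultiOmicsDataset: aligned multi-view matrices with binary response
#'
#' Container for an ordered collection of [OmicsView-class] objects sharing
#' one sample ordering, plus a binary drug-response label per sample
#' (1 = responder, 0 = non-responder).
#'
#' @slot views list of `OmicsView`, all with identical sample ordering.
#' @slot response integer vector of 0/1 labels, named by sample ID.
#' @slot name single character dataset label.
#' @slot metadata free-form list (e.g. the generating synthetic spec).
#'
#' @seealso [MultiOmicsDataset()], [alignViews()], [generateMultiOmics()].
#' @export
setClass("MultiOmicsDataset",
  representation(
    views = "list",
    response = "integer",
    name = "character",
    metadata = "list"
  )
)

setValidity("MultiOmicsDataset", function(object) {
  msg <- character()
  if (length(object@views) < 1L)
    msg <- c(msg, "at least one view is required")
  if (!all(vapply(object@views, is, logical(1), "OmicsView")))
    msg <- c(msg, "'views' must all be OmicsView objects")
  ids <- names(object@response)
  if (is.null(ids))
    msg <- c(msg, "'response' must be named by sample ID")
  if (!all(object@response %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  for (v in object@views) {
    if (!is(v, "OmicsView")) next
    if (nrow(v@matrix) != length(object@response) ||
        !identical(rownames(v@matrix), ids))
      msg <- c(msg, sprintf(
        "view '%s' is not aligned with the response sample order", v@name))
  }
  if (length(msg)) msg else TRUE
})

#' TrainedModel: a fitted multi-omics classifier
#'
#' Opaque result of [fitArchitecture()]. Exposes responder probabilities via
#' [predictResponse()] and, where the architecture defines one, a per-view
#' latent embedding via [embedSamples()]. Parameters are stored as plain
#' numeric matrices so models serialize to text.
#'
#' @slot kind architecture identifier (see [architectureKinds()]).
#' @slot variant Omics Stacking variant, `"standard"` for other kinds.
#' @slot hp the hyperparameter set (named list) used for training.
#' @slot seed integer seed that makes training reproducible.
#' @slot params named list of numeric parameter matrices.
#' @slot meta architecture bookkeeping (view names, widths, PCA rotations,
#'   combiner coefficients, ...).
#' @slot trainingLog data.frame of per-epoch training losses.
#' @export
setClass("TrainedModel",
  representation(
    kind = "character",
    variant = "character",
    hp = "list",
    seed = "integer",
    params = "list",
    meta = "list",
    trainingLog = "data.frame"
  )
)

setValidity("TrainedModel", function(object) {
  if (length(object@kind) != 1L) return("'kind' must be a single string")
  TRUE
})
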