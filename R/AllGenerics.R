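#' @rdname MultiOmicsDataset-class
#' @param x a `MultiOmicsDataset` (or, where noted, an `OmicsView`).
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))

#' @rdname MultiOmicsDataset-class
#' @param name view name.
#' @export
setGeneric("getView", function(x, name) standardGeneric("getView"))

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("views", function(x) standardGeneric("views"))

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname OmicsView-class
#' @param x an `OmicsView`.
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname OmicsView-class
#' @export
setGeneric("viewMatrix", function(x) standardGeneric("viewMatrix"))

#' @rdname OmicsView-class
#' @export
setGeneric("encoding", function(x) standardGeneric("encoding"))

#' Predict responder probabilities from a fitted model
#'
#' @param object a [TrainedModel-class].
#' @param data a [MultiOmicsDataset-class] whose views match the feature
#'   spaces the model was trained on.
#' @return numeric vector of responder probabilities in `[0, 1]`, one per
#'   sample, named by sample ID.
#' @export
setGeneric("predictResponse",
           function(object, data) standardGeneric("predictResponse"))

#' Latent embedding of samples under a fitted model
#'
#' Returns the concatenated per-view latent representation where the
#' architecture defines one (all kinds except early integration, whose
#' single hidden layer is returned as its embedding, and PCA, whose
#' concatenated principal-component scores are returned).
#'
#' @inheritParams predictResponse
#' @return numeric matrix, samples x latent dimensions.
#' @export
setGeneric("embedSamples",
           function(object, data) standardGeneric("embedSamples"))
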