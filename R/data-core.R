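#' Construct an OmicsView
#'
#' @param name view identifier, e.g. `"expression"`.
#' @param matrix numeric samples x features matrix with sample IDs as
#'   rownames and unique feature IDs as colnames.
#' @param encoding `"continuous"` or `"binary"`.
#' @return an [OmicsView-class].
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
#' OmicsView("expression", m, "continuous")
#' @export
OmicsView <- function(name, matrix, encoding = c("continuous", "binary")) {
  encoding <- match.arg(encoding)
  storage.mode(matrix) <- "double"
  new("OmicsView", name = name, matrix = matrix, encoding = encoding)
}

#' Construct a MultiOmicsDataset
#'
#' Views must already share the response's sample ordering; use
#' [alignViews()] to reorder and validate arbitrary inputs.
#'
#' @param views list of [OmicsView-class] objects.
#' @param response numeric/integer 0-1 vector named by sample ID
#'   (1 = responder).
#' @param name dataset label.
#' @param metadata free-form list attached to the dataset.
#' @return a [MultiOmicsDataset-class].
#' @export
MultiOmicsDataset <- function(views, response, name = "dataset",
                              metadata = list()) {
  if (is(views, "OmicsView")) views <- list(views)
  resp <- as.integer(response)
  names(resp) <- names(response)
  names(views) <- vapply(views, function(v) v@name, character(1))
  new("MultiOmicsDataset", views = views, response = resp, name = name,
      metadata = metadata)
}

## ---- accessors -----------------------------------------------------------

#' @rdname MultiOmicsDataset-class
#' @export
setMethod("viewNames", "MultiOmicsDataset",
          function(x) vapply(x@views, function(v) v@name, character(1)))

#' @rdname MultiOmicsDataset-class
#' @export
setMethod("views", "MultiOmicsDataset", function(x) x@views)

#' @rdname MultiOmicsDataset-class
#' @export
setMethod("getView", "MultiOmicsDataset", function(x, name) {
  i <- match(name, viewNames(x))
  if (is.na(i)) stop("no view named '", name, "'")
  x@views[[i]]
})

#' @rdname MultiOmicsDataset-class
#' @export
setMethod("responseLabels", "MultiOmicsDataset", function(x) x@response)

#' @rdname MultiOmicsDataset-class
#' @export
setMethod("sampleIDs", "MultiOmicsDataset", function(x) names(x@response))

#' @rdname OmicsView-class
#' @export
setMethod("featureIDs", "OmicsView", function(x) colnames(x@matrix))

#' @rdname OmicsView-class
#' @export
setMethod("viewMatrix", "OmicsView", function(x) x@matrix)

#' @rdname OmicsView-class
#' @export
setMethod("encoding", "OmicsView", function(x) x@encoding)

#' @rdname OmicsView-class
#' @export
setMethod("sampleIDs", "OmicsView", function(x) rownames(x@matrix))

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s' (%s): %d samples x %d features\n",
              object@name, object@encoding,
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  n <- length(object@response)
  cat(sprintf("MultiOmicsDataset '%s': %d samples (%d responders), %d views\n",
              object@name, n, sum(object@response), length(object@views)))
  for (v in object@views)
    cat(sprintf("  %-12s %s, %d features\n", v@name, v@encoding,
                ncol(v@matrix)))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s%s (seed %d, %d parameter blocks)\n",
              object@kind,
              if (object@variant != "standard")
                paste0(" [", object@variant, "]") else "",
              object@seed, length(object@params)))
})

## ---- variance filter -----------------------------------------------------

#' Remove low-variance features from a view
#'
#' Keeps exactly the features whose sample variance is strictly greater
#' than `threshold`, preserving column order. The population convention
#' (divide by n) is used by default: the filter is a screening device, not
#' an inference, and the population form makes a constant column's variance
#' exactly zero for any n.
#'
#' @param view an [OmicsView-class].
#' @param threshold non-negative removal bound; features with variance
#'   `<= threshold` are dropped.
#' @param population logical; divide by n (default) rather than n - 1.
#' @return the filtered [OmicsView-class].
#' @examples
#' m <- cbind(const = rep(1, 4), varies = c(0, 1, 0, 1))
#' rownames(m) <- paste0("s", 1:4)
#' v <- OmicsView("mutation", m, "binary")
#' featureIDs(varianceFilter(v, 0))
#' @export
varianceFilter <- function(view, threshold = 0, population = TRUE) {
  stopifnot(is(view, "OmicsView"), threshold >= 0)
  m <- view@matrix
  if (ncol(m) < 1L) stop("view '", view@name, "' has no features")
  n <- nrow(m)
  v <- apply(m, 2L, stats::var) * (if (population) (n - 1) / n else 1)
  keep <- v > threshold
  if (!any(keep))
    stop("empty view after filtering: all ", ncol(m), " features of view '",
         view@name, "' have variance <= ", threshold)
  OmicsView(view@name, m[, keep, drop = FALSE], view@encoding)
}

## ---- alignment -----------------------------------------------------------

#' Align views to a response's sample order
#'
#' Reorders the rows of every view to the ordering of the response vector
#' (the single source of truth for sample order) and assembles a
#' [MultiOmicsDataset-class]. Every view must cover exactly the response's
#' sample IDs, in any order.
#'
#' @param views list of [OmicsView-class] objects (or a single view).
#' @param response 0-1 vector named by sample ID.
#' @param name dataset label.
#' @return a [MultiOmicsDataset-class].
#' @export
alignViews <- function(views, response, name = "dataset") {
  if (is(views, "OmicsView")) views <- list(views)
  ids <- names(response)
  if (is.null(ids)) stop("response must be named by sample ID")
  for (v in views) {
    vids <- rownames(v@matrix)
    missing_in_view <- setdiff(ids, vids)
    extra_in_view <- setdiff(vids, ids)
    if (length(missing_in_view) || length(extra_in_view))
      stop("alignment error for view '", v@name, "': ",
           if (length(missing_in_view))
             paste0("missing [", paste(missing_in_view, collapse = ", "), "] ")
           else "",
           if (length(extra_in_view))
             paste0("unmatched [", paste(extra_in_view, collapse = ", "), "]")
           else "")
  }
  views <- lapply(views, function(v)
    OmicsView(v@name, v@matrix[ids, , drop = FALSE], v@encoding))
  MultiOmicsDataset(views, response, name = name)
}

## ---- subsetting ----------------------------------------------------------

#' Subset a dataset by sample index
#'
#' @param x a [MultiOmicsDataset-class].
#' @param i integer or logical sample index.
#' @return the subset dataset, views kept aligned.
#' @export
subsetSamples <- function(x, i) {
  resp <- x@response[i]
  views <- lapply(x@views, function(v)
    OmicsView(v@name, v@matrix[i, , drop = FALSE], v@encoding))
  MultiOmicsDataset(views, resp, name = x@name)
}

## ---- file I/O ------------------------------------------------------------

#' Read an omics matrix file
#'
#' Tab- or comma-separated text with the first column holding sample IDs
#' and the header row holding feature IDs; one file per view.
#'
#' @param file path.
#' @param name view name.
#' @param encoding `"continuous"` or `"binary"`.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return an [OmicsView-class].
#' @export
readOmicsView <- function(file, name, encoding = c("continuous", "binary"),
                          sep = NULL) {
  encoding <- match.arg(encoding)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  OmicsView(name, as.matrix(df), encoding)
}

#' @rdname readOmicsView
#' @param view an [OmicsView-class] to write.
#' @export
writeOmicsView <- function(view, file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- data.frame(sample_id = rownames(view@matrix), view@matrix,
                   check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a binary response file
#'
#' Two-column text file: sample ID, label in {0, 1}.
#'
#' @param file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return named integer 0/1 vector.
#' @export
readResponse <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE)
  labels <- as.integer(df[[2L]])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  names(labels) <- as.character(df[[1L]])
  labels
}

#' @rdname readResponse
#' @param response named 0/1 vector.
#' @export
writeResponse <- function(response, file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- data.frame(sample_id = names(response),
                   response = as.integer(response))
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
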