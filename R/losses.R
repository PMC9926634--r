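## Training objectives: online all-triplets mining, triplet loss, the MOLI
## composite loss, and the variational embedding / total losses used by
## OmiEmbed. These are the numeric contracts; the trainers compute the same
## quantities through the autodiff tape.

#' Enumerate all valid triplets of a batch
#'
#' Online all-triplets mining: every ordered (anchor, positive, negative)
#' index triple with anchor != positive, anchor and positive of the same
#' class, and negative of the opposite class. The count is
#' `sum_c n_c (n_c - 1) (n - n_c)` over classes `c`.
#'
#' @param labels binary 0/1 vector (batch labels).
#' @param warn warn when no triplet exists (a class with fewer than two
#'   members, or a single-class batch); the triplet loss then contributes 0.
#' @return integer matrix with columns `anchor`, `positive`, `negative`
#'   (0 rows when no valid triplet exists).
#' @examples
#' nrow(mineAllTriplets(c(1, 1, 0, 0)))  # 8
#' @export
mineAllTriplets <- function(labels, warn = TRUE) {
  stopifnot(all(labels %in% c(0, 1)))
  idx <- seq_along(labels)
  out <- list()
  for (cls in c(0, 1)) {
    pos <- idx[labels == cls]
    neg <- idx[labels != cls]
    np <- length(pos); nn <- length(neg)
    if (np < 2L || nn < 1L) next
    a <- rep(pos, times = np)
    p <- rep(pos, each = np)
    keep <- a != p
    a <- a[keep]; p <- p[keep]
    out[[length(out) + 1L]] <- cbind(
      anchor = rep(a, times = nn),
      positive = rep(p, times = nn),
      negative = rep(neg, each = length(a)))
  }
  if (!length(out)) {
    if (warn) warning("no valid triplets in batch; triplet loss is 0")
    return(matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("anchor", "positive", "negative"))))
  }
  res <- do.call(rbind, out)
  storage.mode(res) <- "integer"
  res
}

#' Triplet loss over mined triplets
#'
#' The hinge loss `sum_i [ ||f(a_i) - f(p_i)||_2^2 - ||f(a_i) - f(n_i)||_2^2
#' + margin ]_+` over the given triplets: squared Euclidean distances, sum
#' (not mean) reduction, clamp at zero. The margin is the minimum squared
#' distance separating opposite-class pairs beyond same-class pairs.
#'
#' @param embeddings numeric batch x d matrix of embedded samples.
#' @param triples integer matrix from [mineAllTriplets()] (columns anchor,
#'   positive, negative).
#' @param margin positive margin.
#' @param reduce `"sum"` (default, as defined) or `"mean"` over triplets.
#' @return non-negative scalar; 0 for an empty triple set.
#' @export
tripletLoss <- function(embeddings, triples, margin, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  embeddings <- as.matrix(embeddings)
  if (nrow(triples) == 0L) return(0)
  stopifnot(max(triples) <= nrow(embeddings), min(triples) >= 1L)
  dap <- rowSums((embeddings[triples[, 1L], , drop = FALSE] -
                  embeddings[triples[, 2L], , drop = FALSE])^2)
  dan <- rowSums((embeddings[triples[, 1L], , drop = FALSE] -
                  embeddings[triples[, 3L], , drop = FALSE])^2)
  h <- pmax(dap - dan + margin, 0)
  if (reduce == "sum") sum(h) else mean(h)
}

#' MOLI composite loss
#'
#' Binary cross-entropy classification loss plus `gamma` times the triplet
#' loss on the concatenated latent representations. At `gamma = 0` the
#' architecture degrades to its pure-classification ablation.
#'
#' @param classificationLoss non-negative binary cross-entropy value.
#' @param triplet non-negative triplet-loss value.
#' @param gamma non-negative triplet weight.
#' @return `classificationLoss + gamma * triplet`.
#' @export
moliLoss <- function(classificationLoss, triplet, gamma) {
  stopifnot(classificationLoss >= 0, triplet >= 0, gamma >= 0)
  classificationLoss + gamma * triplet
}

#' Variational embedding loss
#'
#' The unsupervised loss of the multi-view variational autoencoder:
#' the mean over views of the per-view binary cross-entropy between input
#' and reconstruction, plus the closed-form KL divergence
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` between the learned latent
#' Gaussian and the standard normal. BCE is computed individually for each
#' of the M views (mean over that view's entries); reconstructions are
#' clipped to `[eps, 1 - eps]` before the log.
#'
#' @param inputs list of numeric matrices with entries in `[0, 1]`.
#' @param reconstructions list shaped like `inputs`, entries in `(0, 1)`.
#' @param mu latent mean vector.
#' @param sigma latent standard deviation vector (positive).
#' @param eps clipping constant for the BCE logs.
#' @return non-negative scalar.
#' @export
omiEmbedLoss <- function(inputs, reconstructions, mu, sigma, eps = 1e-7) {
  stopifnot(length(inputs) == length(reconstructions), all(sigma > 0))
  bce <- mapply(function(x, r) {
    if (any(r < 0) || any(r > 1))
      stop("reconstruction values outside [0, 1]")
    if (any(x < 0) || any(x > 1))
      stop("input values outside [0, 1]; rescale continuous views first")
    r <- pmin(pmax(r, eps), 1 - eps)
    -mean(x * log(r) + (1 - x) * log(1 - r))
  }, inputs, reconstructions)
  kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))
  mean(bce) + kl
}

#' Total variational-classifier loss
#'
#' @param embed the embedding loss ([omiEmbedLoss()]).
#' @param taskCE the downstream cross-entropy loss.
#' @param lambda non-negative balancing weight on the embedding term.
#' @return `lambda * embed + taskCE`.
#' @export
omiEmbedTotalLoss <- function(embed, taskCE, lambda) {
  stopifnot(embed >= 0, taskCE >= 0, lambda >= 0)
  lambda * embed + taskCE
}

## numeric BCE used across trainers (probabilities, clipped)
bceLoss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
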