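## Minimal matrix-valued reverse-mode automatic differentiation.
##
## A tape records operation nodes in creation order; backward() walks the
## tape in reverse, pushing gradients to parents. Nodes are environments:
##   val     numeric matrix (value)
##   grad    accumulated gradient (same shape), NULL until touched
##   parents list of parent nodes
##   backfn  function(g, node) -> list of parent gradients (NULL entries
##           for parents that do not require gradients)
##   track   logical; FALSE for constants, skips gradient computation
## Parameters are off-tape leaf nodes with track = TRUE; their grads are
## what the optimizer consumes. Internal — not exported.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

adNode <- function(val, parents = list(), backfn = NULL, tape = NULL,
                   track = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$track <- if (is.null(track))
    any(vapply(parents, function(p) isTRUE(p$track), logical(1)))
  else track
  if (!is.null(tape) && n$track) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- n
  }
  n
}

adParam <- function(val) adNode(val, track = TRUE)
adConst <- function(val) adNode(val, track = FALSE)

accGrad <- function(node, g) {
  if (!isTRUE(node$track)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

## Seed must be a scalar node (1x1).
adBackward <- function(tape, loss) {
  accGrad(loss, matrix(1, 1, 1))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    for (j in seq_along(nd$parents))
      if (!is.null(gs[[j]])) accGrad(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- operations ----------------------------------------------------------

adMatmul <- function(a, b, tape) {
  adNode(a$val %*% b$val, list(a, b), tape = tape,
         backfn = function(g, nd) list(
           if (a$track) g %*% t(b$val) else NULL,
           if (b$track) t(a$val) %*% g else NULL))
}

## bias: 1 x k parameter broadcast over rows of a (n x k)
adAddBias <- function(a, bias, tape) {
  adNode(sweep(a$val, 2L, as.vector(bias$val), "+"), list(a, bias),
         tape = tape,
         backfn = function(g, nd) list(
           if (a$track) g else NULL,
           if (bias$track) matrix(colSums(g), 1L) else NULL))
}

adAdd <- function(a, b, tape) {
  adNode(a$val + b$val, list(a, b), tape = tape,
         backfn = function(g, nd) list(if (a$track) g else NULL,
                                       if (b$track) g else NULL))
}

adSub <- function(a, b, tape) {
  adNode(a$val - b$val, list(a, b), tape = tape,
         backfn = function(g, nd) list(if (a$track) g else NULL,
                                       if (b$track) -g else NULL))
}

adMul <- function(a, b, tape) {
  adNode(a$val * b$val, list(a, b), tape = tape,
         backfn = function(g, nd) list(
           if (a$track) g * b$val else NULL,
           if (b$track) g * a$val else NULL))
}

adScale <- function(a, s, tape) {           # s plain scalar
  adNode(a$val * s, list(a), tape = tape,
         backfn = function(g, nd) list(g * s))
}

adAddConst <- function(a, c, tape) {        # c plain scalar or matrix
  adNode(a$val + c, list(a), tape = tape,
         backfn = function(g, nd) list(g))
}

adRelu <- function(a, tape) {
  m <- a$val > 0
  adNode(a$val * m, list(a), tape = tape,
         backfn = function(g, nd) list(g * m))
}

adSigmoid <- function(a, tape) {
  s <- 1 / (1 + exp(-a$val))
  adNode(s, list(a), tape = tape,
         backfn = function(g, nd) list(g * s * (1 - s)))
}

adExp <- function(a, tape) {
  e <- exp(a$val)
  adNode(e, list(a), tape = tape,
         backfn = function(g, nd) list(g * e))
}

adLog <- function(a, tape) {
  adNode(log(a$val), list(a), tape = tape,
         backfn = function(g, nd) list(g / a$val))
}

adSum <- function(a, tape) {
  dims <- dim(a$val)
  adNode(matrix(sum(a$val), 1, 1), list(a), tape = tape,
         backfn = function(g, nd) list(matrix(g[1], dims[1], dims[2])))
}

adMean <- function(a, tape) {
  dims <- dim(a$val)
  nel <- prod(dims)
  adNode(matrix(sum(a$val) / nel, 1, 1), list(a), tape = tape,
         backfn = function(g, nd) list(matrix(g[1] / nel, dims[1], dims[2])))
}

adRowSums <- function(a, tape) {            # n x d -> n x 1
  d <- ncol(a$val)
  adNode(matrix(rowSums(a$val), ncol = 1L), list(a), tape = tape,
         backfn = function(g, nd) list(matrix(g, nrow(g), d)))
}

adCbind <- function(nodes, tape) {
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  adNode(do.call(cbind, lapply(nodes, function(n) n$val)), nodes,
         tape = tape,
         backfn = function(g, nd)
           lapply(seq_along(nodes), function(j)
             if (nodes[[j]]$track)
               g[, starts[j]:ends[j], drop = FALSE] else NULL))
}

adRows <- function(a, idx, tape) {          # gather rows
  nr <- nrow(a$val); nc <- ncol(a$val)
  adNode(a$val[idx, , drop = FALSE], list(a), tape = tape,
         backfn = function(g, nd) {
           da <- matrix(0, nr, nc)
           agg <- rowsum(g, group = idx)
           da[as.integer(rownames(agg)), ] <- agg
           list(da)
         })
}

## inverted dropout; mask drawn from the session RNG at build time
adDropout <- function(a, rate, tape, train = TRUE) {
  if (!train || rate <= 0) return(a)
  keep <- matrix(stats::runif(length(a$val)) >= rate,
                 nrow(a$val), ncol(a$val)) / (1 - rate)
  adNode(a$val * keep, list(a), tape = tape,
         backfn = function(g, nd) list(g * keep))
}

adSoftmaxRows <- function(a, tape) {
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  adNode(s, list(a), tape = tape,
         backfn = function(g, nd) list(s * (g - rowSums(g * s))))
}

## L2-normalize each row to unit norm
adRowNormalize <- function(a, tape, eps = 1e-12) {
  r <- sqrt(rowSums(a$val^2)) + eps
  v <- a$val / r
  adNode(v, list(a), tape = tape,
         backfn = function(g, nd)
           list(g / r - a$val * (rowSums(g * a$val) / r^3)))
}

## numerically stable binary cross-entropy on logits; y constant 0/1 matrix
## (targets may be fractional for reconstruction losses); mean reduction
adBCELogits <- function(z, y, tape) {
  zv <- z$val
  sp <- pmax(zv, 0) + log1p(exp(-abs(zv)))   # softplus(z)
  nel <- length(zv)
  adNode(matrix(sum(sp - y * zv) / nel, 1, 1), list(z), tape = tape,
         backfn = function(g, nd)
           list((1 / (1 + exp(-zv)) - y) * (g[1] / nel)))
}

## per-sample pairwise module attention for one (u, v) view pair.
## au, av: (n*K) x 2 stacks of unit module vectors, sample-major blocks.
## Returns the attended representation of view u: softmax_rows(au av^T) av
## computed blockwise per sample.
adAttention <- function(au, av, K, tape) {
  n <- nrow(au$val) / K
  out <- matrix(0, n * K, 2L)
  Ss <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * K + 1L):(i * K)
    C <- au$val[rows, , drop = FALSE] %*% t(av$val[rows, , drop = FALSE])
    C <- C - apply(C, 1L, max)
    E <- exp(C)
    S <- E / rowSums(E)
    Ss[[i]] <- S
    out[rows, ] <- S %*% av$val[rows, , drop = FALSE]
  }
  adNode(out, list(au, av), tape = tape,
         backfn = function(g, nd) {
           dau <- matrix(0, n * K, 2L)
           dav <- matrix(0, n * K, 2L)
           for (i in seq_len(n)) {
             rows <- ((i - 1L) * K + 1L):(i * K)
             S <- Ss[[i]]
             gO <- g[rows, , drop = FALSE]
             Av <- av$val[rows, , drop = FALSE]
             Au <- au$val[rows, , drop = FALSE]
             dS <- gO %*% t(Av)
             dav[rows, ] <- dav[rows, ] + t(S) %*% gO
             dC <- S * (dS - rowSums(dS * S))
             dau[rows, ] <- dau[rows, ] + dC %*% Av
             dav[rows, ] <- dav[rows, ] + t(dC) %*% Au
           }
           list(if (au$track) dau else NULL,
                if (av$track) dav else NULL)
         })
}

## reshape n x 2K (module coordinates interleaved as [x1..xK, y1..yK])
## into the (n*K) x 2 sample-major stack used by adAttention
adStackModules <- function(a, K, tape) {
  n <- nrow(a$val)
  x <- as.vector(t(a$val[, 1:K, drop = FALSE]))
  y <- as.vector(t(a$val[, (K + 1):(2 * K), drop = FALSE]))
  adNode(cbind(x, y, deparse.level = 0), list(a), tape = tape,
         backfn = function(g, nd) {
           da <- matrix(0, n, 2L * K)
           da[, 1:K] <- t(matrix(g[, 1], nrow = K))
           da[, (K + 1):(2 * K)] <- t(matrix(g[, 2], nrow = K))
           list(da)
         })
}

## inverse of adStackModules: (n*K) x 2 -> n x 2K
adUnstackModules <- function(a, K, tape) {
  n <- nrow(a$val) / K
  out <- cbind(t(matrix(a$val[, 1], nrow = K)),
               t(matrix(a$val[, 2], nrow = K)))
  adNode(out, list(a), tape = tape,
         backfn = function(g, nd) {
           da <- cbind(as.vector(t(g[, 1:K, drop = FALSE])),
                       as.vector(t(g[, (K + 1):(2 * K), drop = FALSE])))
           list(da)
         })
}

## ---- optimizer -----------------------------------------------------------

## Adagrad with decoupled-from-nothing classic L2 penalty: the weight-decay
## term enters the gradient before the per-parameter adaptive step, matching
## an adaptive first-order optimizer with L2 regularization.
adagradInit <- function(params) {
  lapply(params, function(p) array(0, dim(p$val)))
}

adagradStep <- function(params, state, lr, weightDecay, eps = 1e-10) {
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- if (is.null(p$grad)) array(0, dim(p$val)) else p$grad
    g <- g + weightDecay * p$val
    state[[k]] <- state[[k]] + g^2
    p$val <- p$val - lr * g / (sqrt(state[[k]]) + eps)
    p$grad <- NULL
  }
  state
}

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## Glorot-uniform initialization
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

denseParams <- function(nin, nout) {
  list(W = adParam(glorot(nin, nout)), b = adParam(matrix(0, 1, nout)))
}

denseForward <- function(x, layer, tape) {
  adAddBias(adMatmul(x, layer$W, tape), layer$b, tape)
}
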