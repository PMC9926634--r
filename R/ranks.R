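## Rank-based comparison statistics: mean-rank tables, the Nemenyi critical
## difference, and the exact two-sided Wilcoxon signed-rank test.

#' Mean ranks of methods across datasets
#'
#' Ranks methods within each dataset column by descending metric value
#' (rank 1 = best), averaging tied positions (fractional ranks, the
#' standard Friedman/Nemenyi convention), then averages ranks per method
#' across datasets.
#'
#' @param values numeric methods x datasets matrix (higher is better);
#'   rownames are method names.
#' @return a `rankTable` list with elements `values`, `ranks` (same shape),
#'   `meanRanks` (per method) and counts `m`, `nDatasets`.
#' @examples
#' v <- rbind(a = c(0.9, 0.8), b = c(0.7, 0.85))
#' meanRanks(v)$meanRanks
#' @export
meanRanks <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("NaN/NA cell at method '", rownames(values)[bad[1L]],
         "', dataset column ", bad[2L])
  }
  ranks <- apply(values, 2L, function(col) rank(-col, ties.method = "average"))
  out <- list(values = values, ranks = ranks,
              meanRanks = rowMeans(ranks),
              m = nrow(values), nDatasets = ncol(values))
  class(out) <- c("rankTable", "list")
  out
}

#' @export
print.rankTable <- function(x, ...) {
  cat(sprintf("rankTable: %d methods x %d datasets\n", x$m, x$nDatasets))
  print(round(sort(x$meanRanks), 2))
  invisible(x)
}

## Studentized range quantiles / sqrt(2) at alpha = 0.05 for m = 2..10
## (the standard two-tailed Nemenyi q values).
.nemenyiQ05 <- c(`2` = 1.959964, `3` = 2.343701, `4` = 2.569032,
                 `5` = 2.727774, `6` = 2.849705, `7` = 2.948319,
                 `8` = 3.030879, `9` = 3.101730, `10` = 3.163684)

#' Nemenyi critical difference
#'
#' `CD = q_alpha(m) * sqrt(m (m + 1) / (6 n))`: two methods differ
#' significantly at level `alpha` when their mean ranks differ by at least
#' CD. The q constants are tabulated for `m` in 2..10 at `alpha = 0.05`.
#'
#' @param m number of methods.
#' @param nDatasets number of datasets the ranks average over.
#' @param alpha significance level (only 0.05 is tabulated).
#' @return the critical difference.
#' @examples
#' nemenyiCD(7, 7)  # ~3.40
#' @export
nemenyiCD <- function(m, nDatasets, alpha = 0.05) {
  if (!isTRUE(all.equal(alpha, 0.05)))
    stop("only alpha = 0.05 is tabulated")
  if (m < 2 || m > 10)
    stop("unsupported method count m = ", m, " (tabulated for 2..10)")
  q <- .nemenyiQ05[[as.character(m)]]
  q * sqrt(m * (m + 1) / (6 * nDatasets))
}

#' Significantly different method pairs
#'
#' @param rt a `rankTable` from [meanRanks()].
#' @param alpha level for [nemenyiCD()].
#' @return data.frame of method pairs with mean-rank difference >= CD.
#' @export
significantPairs <- function(rt, alpha = 0.05) {
  cd <- nemenyiCD(rt$m, rt$nDatasets, alpha)
  mr <- rt$meanRanks
  prs <- utils::combn(names(mr), 2L, simplify = FALSE)
  rows <- Filter(function(p) abs(mr[p[1]] - mr[p[2]]) >= cd, prs)
  data.frame(
    method1 = vapply(rows, `[`, "", 1L),
    method2 = vapply(rows, `[`, "", 2L),
    diff = vapply(rows, function(p) unname(abs(mr[p[1]] - mr[p[2]])),
                  numeric(1)),
    cd = rep(cd, length(rows)))
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Computes the exact two-sided p value of the signed-rank statistic
#' `W+ = sum of ranks of positive differences` under the null that every
#' sign pattern of the observed magnitudes is equally likely. Zeros are
#' dropped before ranking; tied magnitudes get average (fractional) ranks.
#' The exact null distribution is obtained by convolving the generating
#' function over doubled ranks, which enumerates all `2^n` sign
#' assignments implicitly and is exact for any tie pattern.
#'
#' @param differences numeric vector of paired differences.
#' @return two-sided p value in `(0, 1]`.
#' @examples
#' wilcoxonSignedRankExact(rep(0.1, 7) + (1:7) / 100)  # 2/128 = 0.015625
#' @export
wilcoxonSignedRankExact <- function(differences) {
  d <- differences[differences != 0]
  if (length(d) == 0L)
    stop("degenerate input: all differences are zero")
  r2 <- 2 * rank(abs(d), ties.method = "average")   # integer-valued
  r2 <- as.integer(round(r2))
  w2 <- sum(r2[d > 0])                              # observed 2 * W+
  total <- sum(r2)
  ## pmf over 2*W+ = 0 .. total via polynomial convolution
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pLe <- sum(pmf[seq_len(w2 + 1L)])
  pGe <- sum(pmf[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(pLe, pGe))
}

#' Count strictly positive differences
#'
#' @param differences numeric vector.
#' @return number of entries strictly greater than zero.
#' @export
countPositive <- function(differences) sum(differences > 0)
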