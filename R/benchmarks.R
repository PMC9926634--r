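#' Bundled reference benchmark tables
#'
#' Per-drug mean AUROC/AUPRC values for the seven integration architectures
#' from a published seven-drug benchmark comparison, shipped as plain CSV
#' so rank statistics ([meanRanks()], [nemenyiCD()]) can be recomputed from
#' them. Three tables are available: cross-validation test AUROC
#' (`"auroc_cv"`), external-test AUROC (`"auroc_external"`) and
#' external-test AUPRC (`"auprc_external"`).
#'
#' @param which one of `"auroc_cv"`, `"auroc_external"`,
#'   `"auprc_external"`.
#' @return numeric methods x drugs matrix (methods in rows), ready for
#'   [meanRanks()].
#' @examples
#' round(meanRanks(referenceBenchmarks("auroc_external"))$meanRanks, 2)
#' @export
referenceBenchmarks <- function(which = c("auroc_cv", "auroc_external",
                                          "auprc_external")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("benchmark_", which, ".csv"),
                      package = "stackOmics", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1L]))
  colnames(m) <- df[[1L]]
  m
}
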