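Package: stackOmics
Title: Neural Multi-Omics Integration Architectures for Drug Response
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements seven multi-omics integration architectures for
    binary drug-response classification -- early integration, per-view PCA
    integration, MOLI, Super.FELT, Omics Stacking (with its ablation
    variants), MOMA and OmiEmbed -- on a common fit/predict/embed contract,
    together with the training objectives they require (online all-triplets
    mining, triplet loss, composite and variational losses). Provides a
    fair-comparison engine with stratified nested cross-validation, random
    hyperparameter search with an upper-bound pruning rule, AUROC/AUPRC
    scoring on test and external splits, rank-based post-hoc statistics
    (mean ranks, Nemenyi critical difference, exact Wilcoxon signed-rank),
    Shapley value sampling attribution aggregated to the omics-view level,
    and a synthetic multi-omics generator with planted class signal and
    configurable class imbalance so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
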