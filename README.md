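# stackOmics

Seven neural and classical multi-omics integration architectures for
binary drug-response prediction, behind one `fit / predict / embed`
contract, with the machinery needed to compare them fairly and to
explain what they use.

Drug-response cohorts pair a handful of omics views over the same
samples — standardized gene expression, binary somatic mutation status,
binary copy-number aberration (CNA) — with a responder / non-responder
label, typically for a few hundred samples of which fewer than 15% are
responders. The architectures differ in where they integrate:

| kind | integration | loss |
|---|---|---|
| `early_integration` | early (concatenate raw features) | BCE |
| `pca` | intermediate (per-view principal components) | BCE |
| `moli` | intermediate (per-view encoders, joint classifier) | BCE + γ·triplet |
| `superfelt` | intermediate, two phases (encode, then classify) | triplet, then BCE |
| `omics_stacking` | intermediate + late (per-view and concatenated heads, meta-learner) | BCE + γ·triplet |
| `moma` | intermediate + late (module attention, per-view outputs, logistic combiner) | CE per view |
| `omiembed` | intermediate (multi-view VAE + downstream classifier) | λ·(BCE + KL) + CE |

The triplet loss is the all-triplets hinge
`Σ_i [‖f(aᵢ)−f(pᵢ)‖² − ‖f(aᵢ)−f(nᵢ)‖² + α]₊` over every valid
(anchor, positive, negative) triple of a minibatch, computed on the
concatenated latent embeddings. Omics Stacking — intermediate *and*
late integration combined through a fully connected meta-learner — also
ships its three ablation variants (`complete_integration`,
`without_integration`, `without_triplet`).

Around the models, the package provides:

- `runComparison()` — stratified 5×5 nested cross-validation, 200-draw
  random hyperparameter search per outer fold from a fixed grid,
  candidate selection by mean inner AUROC under an upper-bound pruning
  rule, retraining on train+validation, AUROC/AUPRC on the test fold
  and an untouched external set;
- `meanRanks()`, `nemenyiCD()`, `wilcoxonSignedRankExact()` — mean-rank
  tables (ties averaged), the Nemenyi critical difference
  `CD = q₀.₀₅(m)·√(m(m+1)/(6n))`, and the exact two-sided Wilcoxon
  signed-rank test;
- `shapleySampling()` / `aggregateViews()` — Shapley value sampling
  attribution (50 permutations by default) aggregated to normalized
  per-view sums and means;
- `generateMultiOmics()` / `makeExternalShifted()` — a synthetic
  generator with planted class signal, realistic imbalance, and a
  covariate-shifted external analogue, so everything above runs and is
  tested fully offline;
- a thin CLI (`inst/scripts/stackomics`) with `generate-data`, `train`,
  `compare`, `rank` and `attribute` subcommands.

All neural kinds run on a small exact reverse-mode autodiff core inside
the package and train with Adagrad + weight decay; training is bit
reproducible given (seed, hyperparameters, data).

## A worked example

```r
library(stackOmics)

spec  <- syntheticSpec(seed = 42)          # 600 samples, 10% responders,
train <- generateMultiOmics(spec, seed = 42)  # views 300/500/500
test  <- generateMultiOmics(spec, seed = 43)
train
#> MultiOmicsDataset 'synthetic': 600 samples (60 responders), 3 views
#>   expression   continuous, 300 features
#>   mutation     binary, 500 features
#>   cna          binary, 500 features

hp <- list(batchSize = 16L, dropout = 0.1, epochs = 20L, gamma = 0.3,
           layerDim = 64L, latentDim = 32L, learningRate = 0.01,
           margin = 0.5, weightDecay = 1e-4, pcaVariance = 0.95)
model <- fitArchitecture(train, "omics_stacking", hp, seed = 1)
p <- predictResponse(model, test)
auroc(p, responseLabels(test))   # 0.828
auprc(p, responseLabels(test))   # 0.498  (chance level = prevalence = 0.10)

A <- shapleySampling(model, subsetSamples(test, 1:25),
                     nPermutations = 20, seed = 1)
round(aggregateViews(A, test)$viewSums, 3)
#> expression   mutation        cna
#>      0.526      0.270      0.204
```

Held-out AUROC 0.83 shows the stack recovers the planted signal well
above the 0.5 chance level; AUPRC 0.50 against a 0.10 prevalence shows
the ranking concentrates responders near the top. The normalized view
attributions sum to one and put the largest share on expression — the
view carrying the strongest planted effect.

Mean ranks and the critical difference over the bundled benchmark
tables:

```r
rt <- meanRanks(referenceBenchmarks("auroc_external"))
round(sort(rt$meanRanks), 2)
#>    omics_stacking         superfelt              moli              moma
#>              2.14              3.14              3.43              4.14
#>               pca          omiembed early_integration
#>              4.14              5.43              5.57
nemenyiCD(7, 7)                  # 3.404
```

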