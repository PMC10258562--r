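# cpae: compositional perturbation autoencoders for single-cell expression

High-throughput single-cell screens measure transcriptional responses to
drug and genetic perturbations, but the combinatorial space of
perturbation x dose x cell-line conditions can never be measured
exhaustively. `cpae` implements the compositional perturbation autoencoder
(CPA): an adversarially disentangled autoencoder that factorizes the
log-normalized expression of each cell into

```
z_i = z_i^basal + V_pert · [f_1(d_i1), …, f_M(d_iM)] + Σ_j V_cov^j · c_ij
```

where `z_i^basal` is a basal state encoded from expression and stripped of
perturbation/covariate information by discriminator networks, `V_pert` is a
dictionary of learned per-perturbation latent embeddings scaled by learned
dose–response curves `f_j` (constrained so `f_j(0) = 0`), and `V_cov^j` are
covariate (cell line, species, patient) dictionaries. A Gaussian decoder
maps the composed latent state back to per-gene means and variances.
Because the factorization is additive in latent space, embeddings can be
recombined at prediction time to answer counterfactual queries — what would
this cell's expression look like under a different drug, dose, combination
or covariate — including condition combinations never observed in training.
A condition-level uncertainty proxy (minimum cosine/euclidean distance
between the queried condition embedding and all training condition
embeddings) flags extrapolations, and a rule-based layer classifies
genetic-interaction modes (epistatic, potentiation, synergy, additive,
redundant) from two-coefficient regressions of double-perturbation
expression deltas on their singles.

The package is aimed at computational biologists analyzing perturbation
scRNA-seq (sci-Plex, Perturb-seq style) who want counterfactual response
prediction, in-silico imputation of unmeasured perturbation pairs, and
interpretable perturbation embeddings, at desk scale and without a GPU.
Data containers build on `SummarizedExperiment`; the neural networks,
adversarial training loop, distance correlation and evaluation harness are
implemented in the package itself.

## Worked example

Simulate a screen with four perturbations and two cell lines, hold out the
`A+B` combination entirely, train, and predict it counterfactually:

```r
library(cpae)

truth  <- syntheticTruth(seed = 21)                 # 200 genes, M = 4, 2 lines
design <- basicDesign(truth, nPerCondition = 150, pairs = list(c("A", "B")))
ds     <- generateDataset(truth, design, seed = 22)$dataset
ds     <- makeSplit(ds, holdoutDesign(ds, list(c("A", "B")),
                                      testFraction = 0.15, seed = 5))

cfg <- cpaConfig(embeddingDim = 12, encoderHidden = 96, encoderLayers = 2,
                 doserHidden = 16, doserLayers = 2, discHidden = 64,
                 discLayers = 2, epochs = 100, batchSize = 96,
                 discSteps = 5, lambdaAdv = 5, lrAE = 1e-3, lrDisc = 1e-3,
                 seed = 501)
model <- trainCpa(ds, cfg)

# counterfactual: control cells of lineA, pushed to dose 1 of A and B
X    <- cellMatrix(ds)
ctrl <- which(conditionIds(ds) == "ctrl|lineA" & splitLabels(ds) == "train")
pred <- predictCondition(model, X[ctrl, ], c(cell_line = "lineA"),
                         c(A = 1, B = 1, C = 0, D = 0))

obs  <- colMeans(X[conditionIds(ds) == "A+B@1+1|lineA", ])
r2Score(obs, pred$mean)
#> [1] 0.907
r2Score(obs, randomBaseline(ds, "A+B@1+1|lineA", seed = 41)$mean)
#> [1] 0.868
```

The model's counterfactual condition mean tracks the held-out combination
(R2 0.91 across the 200 genes) ahead of the random-training-subset
baseline (0.87). Conditions seen in training score an uncertainty of exactly zero;
unseen combinations score positive:

```r
conditionUncertainty(model, c(A = 1, B = 0, C = 0, D = 0),
                     c(cell_line = "lineA"), ds)[c("uCosine", "uEuclidean")]
#> $uCosine    [1] 0
#> $uEuclidean [1] 0
```

`imputeAllPairs()` iterates every unmeasured perturbation pair, predicts
its condition mean and attaches this uncertainty;
`countMissingPairs(105, 131)` reproduces the bookkeeping of a 105-gene
Perturb-seq screen with 131 measured pairs: 5,329 missing combinations,
97.6% of all possibilities. `computeDeltas()`, `interactionMetrics()` and
`classifyMode()` implement the genetic-interaction panel
(c1/c2 regression, magnitude, dominance, distance correlations, rule-based
modes).

See the methods vignette (`vignettes/compositional-perturbation-modeling.Rmd`)
for the model, the training dynamics, every tunable that matters, and the
synthetic generator's scope.

## Command-line use

`inst/scripts/cpa-tool.R` exposes `simulate`, `train`, `predict`,
`evaluate` and `gi` subcommands over a shared YAML config; each run writes
a JSON manifest next to its outputs.

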