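# ddinet

Multiclass prediction of drug–drug interaction (DDI) *types* from fused
drug similarity networks.

When two drugs are taken together, the interaction is not just present or
absent — it has a type ("metabolism decreased", "risk of adverse effects
increased", ...). `ddinet` implements a network-fusion pipeline that
predicts the interaction type of a drug pair from heterogeneous drug
annotations, for computational pharmacologists who want to triage candidate
pairs before experimental or clinical follow-up. It is equally usable as a
testbed: a planted-group synthetic generator, cold-start cross-validation
scenes and ablation variants are first-class parts of the package.

## The method

Five drug–drug similarity networks are built over a catalog of *m* drugs:

1. **Jaccard networks** (4): for each binary annotation profile — chemical
   substructure bits, target, pathway and enzyme associations — the
   similarity of drugs *i, j* with descriptor sets *A, B* is
   *s(i,j) = |A ∩ B| / |A ∪ B|*.
2. **ATC network** (1): WHO ATC codes are split into their 5 hierarchy
   levels; two codes score *k/5* where *k* is the length of the common
   level prefix; a drug pair scores the maximum over its code pairs.

Each similarity matrix *S* is converted into a *topological* similarity
network: rows are normalized to a transition matrix *W = D⁻¹S*, a random
walk with restart *pₜ = α pₜ₋₁ W + (1−α) p₀* (restart probability
α = 0.8, L1 tolerance ε = 10⁻⁹) is run from every drug, and the stacked
diffusion states *P* are re-expressed as positive pointwise mutual
information *X(i,j) = max(0, log₂ P(i,j)·T / (rᵢ·cⱼ))*, symmetrized by
averaging *X* and *Xᵀ*. This yields networks N1…N5 that encode each drug's
global network context rather than its raw neighbour overlaps.

The five networks are fused by a **multimodal deep autoencoder**: one
sigmoid encoder branch per network (m → d), concatenation, a shared
integration layer down to the unified embedding (5d → d_u), and a mirrored
decoder reconstructing every network, trained jointly by Adam on the
summed mean squared reconstruction error. The bottleneck rows are the
unified drug embeddings.

A pair (i, j) is represented by concatenating (or elementwise multiplying
or adding) the two drugs' embeddings and classified by a **softmax deep
neural network** (linear → batch-norm → ReLU → dropout hidden layers,
cross-entropy loss, Adam, early stopping). Evaluation runs fivefold
cross-validation in three scenes: S1 (hide pairs among known drugs),
S2 (one drug of each test pair unseen), S3 (both unseen — full cold
start), reporting one-vs-rest accuracy, macro precision/recall/F1 and
micro AUPR/AUC.

## Worked example

Generate the default synthetic benchmark (80 drugs in 4 latent groups,
5 interaction types, 5% label noise, 1896 labeled pairs) and evaluate the
full pipeline under S1:

```r
library(ddinet)
dataset <- generate_dataset(synth_config(seed = 1))
config  <- benchmark_config(cv = list(scene = "S1", seed = 1))
report  <- run_cv(dataset, config)
print(report)
#> <cv_report> scene S1, 5 folds
#>   acc                0.9816 (sd 0.0027)
#>   acc_plain          0.9541 (sd 0.0068)
#>   precision_macro    0.9550 (sd 0.0063)
#>   recall_macro       0.9536 (sd 0.0074)
#>   f1_macro           0.9543 (sd 0.0069)
#>   f1_macro_perclass  0.9540 (sd 0.0069)
#>   precision_micro    0.9541 (sd 0.0068)
#>   recall_micro       0.9541 (sd 0.0068)
#>   aupr_micro         0.9305 (sd 0.0100)
#>   auc_micro          0.9699 (sd 0.0034)
report$chance_f1_macro
#> [1] 0.2
```

The macro-F1 of 0.95 against a chance level of 0.20 shows the pipeline
recovering the planted group-pair → type rule almost perfectly; the
residual ~5% error matches the generator's label-noise rate (flipped
labels are unpredictable by construction). `acc` is the mean one-vs-rest
accuracy over classes; `acc_plain` is ordinary multiclass accuracy.

Individual stages are exported (`jaccard_similarity`, `atc_similarity`,
`rwr`, `ppmi`, `train_mda`, `train_dnn`, `rank_novel_pairs`, ...):

```r
W <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)   # two-drug toy graph
rwr(W, alpha = 0.8)$values[1, ]
#> [1] 0.5555556 0.4444444                      # closed form: 5/9, 4/9
```

A command-line wrapper with subcommands (`simulate`, `featurize`,
`embed-networks`, `fuse`, `evaluate`, `ablate`, `rank-novel`, `run`) is
installed at `system.file("cli/ddinet.R", package = "ddinet")`.

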