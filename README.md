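# deltamol

Pairwise difference ("delta") machine learning for molecular properties in R.

## The problem

Lead optimization rarely asks "what is the clearance of this molecule?" —
it asks "will this modification *improve* the clearance?". The usual route
is to train a single-molecule regressor f(x) on absolute property values
and score a modification by subtraction, f(y) − f(x). `deltamol`
implements the alternative: train directly on **ordered molecule pairs**
whose target is the property difference,

    Δ(x, y) = v(y) − v(x),

so the model D(x, y) learns property *changes* from the quadratically
expanded pair data. The package provides, end to end:

- **Curation** (`curate_dataset`): qualifier ("<"/">") and invalid-SMILES
  filtering, OpenBabel canonicalization, within-dataset structure
  deduplication (keep first), log10/identity transforms, and a per-rule
  provenance log; `dedup_against` removes external-set molecules identical
  (fingerprint Tanimoto ≥ threshold) to a training set.
- **Leak-free pairing** (`make_fold_plan`, `pairs_for_fold`): molecules are
  split into repeated k-fold partitions *before* exhaustive cross-merging,
  so no molecule contributes pairs to both train and test
  (`leakage_check` asserts it). Self pairs and both orientations are kept
  by default.
- **Models** (a single `predict_delta(model, pairs)` contract):
  - traditional predict-then-subtract: random forest (500 trees) and
    gradient boosting on 2048-bit radius-2 Morgan-style circular
    fingerprints;
  - `gbm_delta`: gradient boosting on concatenated pair fingerprints
    (first ‖ second, 4096 bits), row-subsampling fraction 0.1;
  - `graph_delta`: a two-encoder directed message passing neural network
    (D-MPNN, sum aggregation, 5 epochs by default) whose per-molecule
    latents are concatenated and fed to a feed-forward head — written in
    plain R with hand-derived backpropagation and Adam.
- **Invariant diagnostics** (`invariant_report`): a perfect difference
  model must satisfy D(x,x) = 0, D(x,y) = −D(y,x), and
  D(x,y) + D(y,z) = D(x,z). Traditional models satisfy all three exactly
  (differences telescope); for delta models the residuals (self-pair MAE,
  swap correlation, triplet-additivity MAE) are label-free quality
  measures, and `anticipate_performance` correlates them with
  cross-validated error across datasets.
- **Evaluation** (`run_cv`, `compute_metrics`): repeated k-fold CV with
  Pearson r / MAE / RMSE / sign accuracy, repeat-level pooling with
  mean ± SD summaries, paired model comparisons, scaffold stratification
  (same vs different Bemis–Murcko scaffold), delta-magnitude deciles and
  similarity-vs-error analysis.
- **Synthetic benchmarks** (`generate_library`): decorated ring scaffolds
  with an exactly additive latent property, tunable Gaussian noise and an
  optional constant assay offset — pairing cancels the offset exactly.

## Worked example

```r
library(deltamol)

ds <- generate_library(generator_config(n_molecules = 200, noise_sd = 0.1,
                                        seed = 7))
plan <- make_fold_plan(ds, n_folds = 10, n_repeats = 1, seed = 7)
split <- pairs_for_fold(plan, 1, 1, ds)
leakage_check(split$train, split$test)
#> [1] TRUE

model <- train_delta_graph(split$train, model_config("graph_delta", seed = 7))
pred <- predict_delta(model, split$test)
compute_metrics(split$test$delta, pred)
#> <metric_report>: r = 0.988, MAE = 0.199, RMSE = 0.247, sign acc = 0.937 (n = 400)
```

The held-out fold's 400 ordered pairs are predicted with Pearson r 0.988
and MAE 0.199 log units — versus 1.180 for always predicting "no change" —
after five epochs on the 32,400 cross-merged training pairs. The same model's
label-free diagnostics:

```r
invariant_report(model, ds[ds$mol_id %in% unique(split$test$first), ])
#> <invariant_report> (20 molecules)
#>   self-pair MAE : 0.1181
#>   swap r        : -0.9917
#>   additivity MAE: 0.1523 (6840 triplets)
```

A traditional model run through the same report gives exactly 0 / −1 / 0:
subtraction telescopes.

## Command line

A thin wrapper (`inst/cli/deltamol.R`) exposes
`generate | curate | pair | cv | train | predict | invariants | report`;
every run writes a JSON manifest with seeds and input digests. Externally
downloaded benchmark tables (a CSV with `smiles` and `value` columns) flow
through the same path, e.g.
`deltamol.R curate --in table.csv --transform log10 --out curated.csv`
followed by `deltamol.R cv --in curated.csv --families gbm_delta,forest_traditional`,
which emits mean ± SD summaries over the CV repeats.

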