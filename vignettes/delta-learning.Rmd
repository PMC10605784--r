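---
title: "Delta learning for molecular property differences: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta learning for molecular property differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task

Molecular optimization is a question about *differences*: given a starting
molecule x and a proposed derivative y, will an ADMET property (clearance,
solubility, permeability, ...) move in the right direction, and by how
much? `deltamol` supports two ways to answer it.

**Traditional (predict-then-subtract).** Fit f on single molecules and
absolute values; score a pair as f(y) − f(x). Any such model, however bad,
has three structural properties *for free*, because its pairwise
differences telescope:

1. self pairs: D(x, x) = f(x) − f(x) = 0, exactly;
2. antisymmetry: D(x, y) = −D(y, x), exactly;
3. additivity: D(x, y) + D(y, z) = D(x, z), to floating precision.

**Delta (direct difference regression).** Fit D directly on ordered pairs
(x, y) with target v(y) − v(x). Pairing expands n molecules into n² ordered
training examples (self pairs included by default), which is the point: the
same small dataset yields quadratically more gradient signal, and a
systematic additive assay error cancels out of every target. The price is
that properties 1–3 are no longer guaranteed — a direct delta model only
*learns* them — which turns them into label-free diagnostics (below).

Sign convention: `delta = value(second) − value(first)` everywhere,
including exported pair CSVs. Only the convention's consistency matters;
antisymmetry makes the direction itself arbitrary.

## Leakage and the pairing firewall

Pairs share molecules, so pair-level random splits leak: a test pair
(a, b) whose molecule a also appears in training pairs is partially
memorized. `make_fold_plan` therefore partitions *molecules* into
`n_repeats` × `n_folds` assignments (default 5 × 10; fold sizes differ by
at most one; each repeat reshuffles with its own sub-seed derived from the
master seed), and `pairs_for_fold` cross-merges train-side and test-side
molecules separately. The train and test pair sets of every fold are
disjoint in molecules by construction; `leakage_check` asserts it, and the
test suite verifies it for every fold of a 5 × 10 plan on 300 molecules.

Both orientations of each unordered pair, and self pairs, are kept in test
sets by default: evaluation is then over exactly n_fold² ordered pairs, and
each unordered pair contributes twice. Both toggles (`include_self_pairs`,
and excluding self pairs from diagnostics where they are uninformative)
are explicit in the API.

## Models

All trained models expose one contract, `predict_delta(model, pairs)`.

**Fingerprints.** 2048-bit, radius-2 circular (Morgan/ECFP4-style)
fingerprints hashed by OpenBabel; one `obabel` process per batch, parsed
bit counts cross-checked against the counts the engine prints, and the
engine's own printed Tanimoto similarities serve as an independent oracle
in the tests. Fingerprints are binary, deterministic in the canonical
structure, and cached per unique SMILES within each call.

**Tree families.** `forest_traditional` is a 500-tree random forest
(ranger backend; `mtry` defaults to the backend's sqrt(p) — R's
convention — and is exposed for users wanting the all-features default of
other ecosystems). `gbm_traditional` and `gbm_delta` are gradient boosting
(xgboost backend, histogram trees grown leafwise to 31 leaves, learning
rate 0.1, 100 rounds, `min_child_weight` 20 lowered to 5 for datasets
under 300 molecules). The delta variant consumes the 4096-bit
concatenation first ‖ second. The "subsample frequency 0.1" convention of
the reference gradient-boosting implementation is realized as a
per-iteration row-subsampling *fraction* of 0.1 (that parameter is what
actually thins the quadratic pair sets; a literal integer period of 0.1
would disable subsampling).

**Graph delta model.** A directed message passing neural network written
directly on matrix primitives (no deep-learning framework; gradients are
hand-derived and verified against finite differences in the test suite).
Per directed bond u→v, the hidden state initializes from
ReLU(W_i [x_u ; e_uv]) and refines for `depth − 1 = 2` steps by summing
incoming bond states (excluding the reverse bond), a linear map W_h, a
skip connection to the initial state, and ReLU; atom states are read out
through W_o and summed into the molecule latent (sum aggregation, making
the latent invariant to atom order; mean available). In delta mode the two
molecules are encoded by *separate* encoders by default
(`encoder_sharing = FALSE`; sharing is a symmetry prior users can enable),
the latents are concatenated and a one-hidden-layer feed-forward head
(width 64) regresses the difference. Targets are standardized during
training and un-standardized at prediction.

Defaults: hidden size 64, depth 3, Adam (lr 1e-3, β 0.9/0.999), batch 256
pairs, **5 epochs** for the delta task and **50** for the traditional
graph model — the delta task sees ~n²/n more examples per epoch and
converges in far fewer passes. Head width/depth, batch size and learning
rate are not dictated by the method; they are exposed in `model_config`
and recorded in run manifests. Atom features are element (10-way one-hot
incl. "other"), degree (one-hot 0..5+), and ring membership; bond features
are bond-order one-hot and a ring-bond flag. Formal charge and
hybridization one-hots are deliberately omitted: they are not reliably
recoverable from the kekulized V2000 route used here, and the synthetic
chemistry is charge-neutral — users fitting charged, exotic chemistry
should treat this as a limitation.

Determinism: every fit is reproducible from `config$seed` (single-threaded
backends, seeded initialization and shuffling); `run_cv` derives a
distinct model seed per (repeat, fold) from the configuration seed.

## Invariant diagnostics

`invariant_report` quantifies properties 1–3 for any model: self-pair MAE
(mean |D(x,x)|), swap correlation (Pearson r between predictions on pairs
and on the same pairs reversed; self pairs excluded as uninformative), and
triplet-additivity MAE over ordered triplets of distinct molecules —
exhaustive up to `max_triplets` (default 1e5; the count is cubic),
otherwise a seeded uniform sample whose seed and size are recorded in the
report. Sampled and exhaustive estimates agree within two standard errors
on a 30-molecule fixture in the tests.

By default diagnostics are computed on *test-fold* molecules (the
train-fold choice is equally valid; pass whichever molecule set you want).
`anticipate_performance` then correlates a diagnostic with a CV metric
across datasets: on synthetic suites spanning noise levels, self-pair MAE
tracks CV MAE with strongly positive (rank) correlation, so the label-free
diagnostic anticipates supervised performance.

## Evaluation choices

- Metrics: Pearson r, MAE, RMSE, and sign accuracy (share of pairs whose
  predicted difference has the true sign). Pairs with a true difference of
  exactly 0 have no sign and are excluded from sign accuracy, with the
  exclusion count reported.
- Aggregation: each metric is computed per repeat over that repeat's
  pooled test-pair predictions, then summarized as mean ± SD over repeats.
  Repeats (not folds) are also the unit for paired model comparisons
  (`compare_models`: paired t-test, Wilcoxon signed-rank, and a KS
  normality check of the paired differences; the user chooses — nothing is
  auto-selected).
- Scaffold stratification: Bemis–Murcko frameworks computed by iterative
  terminal-atom pruning plus restoration of multiply-bonded direct
  attachments, then canonical SMILES emission via OpenBabel. An acyclic
  molecule's scaffold is the empty string, and empty equals empty —
  relevant only for acyclic-rich sets. Formal charge on pruned neighbours
  is dropped; scaffold *equality* (all this package uses) is unaffected.
- Magnitude deciles: groups are exactly ⌊0.1 n⌋ pairs; ties at the
  boundary break by input position (stable sort).

## The synthetic generator

`generate_library` decorates six ring cores (benzene, pyridine,
cyclohexane, furan, thiophene, naphthalene) with up to three substituents
drawn from twelve fragments (halogens, alkyls, hydroxy, amino, methoxy,
cyano, carboxyl, ...), giving several thousand distinct structures. The
latent value is scaffold base + Σ fragment contributions — an exactly
additive structure–activity landscape on a log-like scale (latent SD ≈
1.3, range ≈ −1..6, emulating log-transformed ADMET endpoints); the
observed value adds Gaussian noise (`noise_sd`, default 0.1) and a
constant `assay_offset`. Defaults target the benchmark regime the package
is meant for: a few hundred to ~1,350 molecules per dataset
(`n_molecules` default 600), multiple Murcko scaffolds per set.

Two numerical choices are deliberate. Contributions and scaffold bases are
multiples of 1/32, and noise draws are quantized to the 2⁻²⁰ grid
(≈ 1e-6, far below any noise level of interest — real assays are reported
at finite precision anyway). All observed values are then dyadic rationals
with small magnitude, so latent sums, every pairwise difference, triplet
telescoping, and the cancellation of any exactly-representable assay
offset (integers, halves, ...) are **bit-exact** in IEEE arithmetic rather
than merely close. The offset-cancellation guarantee — pair CSVs are
byte-identical and CV metrics are identical with and without a constant
offset — holds exactly for this reason.

What passing tests on this generator do **not** show: real ADMET data has
correlated noise, activity cliffs, non-additive substituent interactions,
heavy-tailed value distributions and far more diverse chemistry. The
synthetic suite validates the *machinery* (leakage firewall, exact
invariants, metric arithmetic, recovery of an additive landscape, the
diagnostics-performance trend); absolute performance numbers on it say
nothing about real benchmarks. Reproducing published benchmark tables
requires the user to download those tables and run them through
`curate_dataset`/`run_cv` (the CLI path in the README); that is supported
but deliberately not part of the test suite, since public dataset versions
drift.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` use 300-molecule datasets
(5–10-fold plans) for the tabular families, a 200-molecule dataset for the
graph model (one fold, ~32k training pairs), and six 150-molecule datasets
across noise SDs 0.05–1.6 for the anticipation experiment. These sizes sit
inside the target regime while keeping a full run at minutes on one CPU;
all of them are plain parameters, and nothing in the code depends on them.

## Known limitations

- OpenBabel's SMILES parser is permissive; a syntactic pre-check (balanced
  brackets, legal characters) catches common corruption, but pathological
  strings that OpenBabel silently "repairs" to a valid molecule pass.
- Scaffold extraction drops formal charges on pruned atoms and does not
  re-aromatize; scaffold strings are consistent within the package but not
  guaranteed identical to other toolkits' Murcko SMILES.
- The graph model is desk-scale: hidden size 64 by default (300-width
  configurations are accepted but slow in plain R), no GPU, no
  uncertainty estimation, no hyperparameter search.
- Duplicate structures within a dataset keep the first record; merging or
  averaging repeated measurements is left to the user's curation
  (`substitutions` handles known notation errors, never guessed ones).
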