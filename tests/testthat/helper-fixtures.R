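# Shared fixtures, built once per test run and memoised. All molecular data
# is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# synthetic dataset of n molecules at a given noise level
synth_ds <- function(n = 50, noise = 0.1, seed = 11, offset = 0) {
  fixture(sprintf("ds_%d_%g_%d_%g", n, noise, seed, offset), function()
    generate_library(generator_config(n_molecules = n, noise_sd = noise,
                                      assay_offset = offset, seed = seed)))
}

# non-molecular records for pure pairing/fold arithmetic (no chemistry);
# values sit on a dyadic grid so difference telescoping is bit-exact
fake_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(mol_id = sprintf("f%04d", seq_len(n)),
             smiles = sprintf("FAKE%04d", seq_len(n)),
             value = round(stats::rnorm(n) * 1024) / 1024,
             stringsAsFactors = FALSE)
}

# traditional models on the shared 50-molecule fixture
trad_forest <- function() fixture("trad_forest", function()
  train_traditional(synth_ds(50), model_config("forest_traditional", seed = 5)))
trad_gbm <- function() fixture("trad_gbm", function()
  train_traditional(synth_ds(50), model_config("gbm_traditional", seed = 5)))

# a small fitted delta model (for invariant residual tests)
small_delta_model <- function() fixture("small_delta_model", function() {
  ds <- synth_ds(60, noise = 0.3, seed = 21)
  plan <- make_fold_plan(ds, n_folds = 3, n_repeats = 1, seed = 21)
  split <- pairs_for_fold(plan, 1, 1, ds)
  train_delta_tabular(split$train, model_config("gbm_delta", seed = 21))
})
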