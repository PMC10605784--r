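# Model families. "Traditional" models regress a single molecule's absolute
# property and obtain pair differences by subtracting two predictions;
# "delta" models regress the difference directly from a paired
# representation. All trained models expose the same contract:
# predict_delta(model, pairs).

MODEL_FAMILIES <- c("forest_traditional", "gbm_traditional", "gbm_delta",
                    "graph_traditional", "graph_delta", "oracle")

#' Model configuration
#'
#' @param family one of `forest_traditional`, `gbm_traditional`, `gbm_delta`,
#'   `graph_traditional`, `graph_delta`, or `oracle` (ground-truth lookup,
#'   for validating evaluation plumbing).
#' @param n_trees random-forest size (default 500).
#' @param subsample_freq per-iteration row subsampling fraction for the
#'   gradient-boosted families (default 0.1, chosen for speed on the
#'   quadratically expanded pair sets).
#' @param n_rounds boosting iterations (default 100).
#' @param learning_rate boosting learning rate (default 0.1).
#' @param max_leaves leaf limit per boosted tree (default 31).
#' @param min_child_samples minimum rows per leaf for boosting (default 20;
#'   automatically lowered to 5 when the training set has fewer than 300
#'   molecules).
#' @param mtry features tried per forest split; `NULL` = `sqrt(p)` default
#'   of the forest backend.
#' @param epochs gradient-descent passes for the graph families; defaults to
#'   5 for `graph_delta` and 50 for `graph_traditional` (the delta task sees
#'   quadratically more examples per epoch and converges much faster).
#' @param hidden_size message/latent width of the graph encoder (default 64).
#' @param depth message-passing steps (default 3).
#' @param ffn_hidden width of the feed-forward head (default 64).
#' @param aggregation atom-to-molecule readout, "sum" (default) or "mean".
#' @param encoder_sharing if `TRUE` the two molecules of a pair share one
#'   encoder's weights (a symmetry prior); default `FALSE`: separate weights.
#' @param batch_size pairs (or molecules) per gradient step (default 256).
#' @param lr Adam learning rate for the graph families (default 1e-3).
#' @param radius,n_bits fingerprint parameters for the fingerprint families.
#' @param seed seed controlling fit randomness.
#' @return a `model_config` list.
#' @export
model_config <- function(family = "gbm_delta",
                         n_trees = 500,
                         subsample_freq = 0.1,
                         n_rounds = 100,
                         learning_rate = 0.1,
                         max_leaves = 31,
                         min_child_samples = 20,
                         mtry = NULL,
                         epochs = NULL,
                         hidden_size = 64,
                         depth = 3,
                         ffn_hidden = 64,
                         aggregation = c("sum", "mean"),
                         encoder_sharing = FALSE,
                         batch_size = 256,
                         lr = 1e-3,
                         radius = 2,
                         n_bits = 2048,
                         seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  aggregation <- match.arg(aggregation)
  if (is.null(epochs))
    epochs <- if (family == "graph_delta") 5L else 50L
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  structure(list(family = family, n_trees = n_trees,
                 subsample_freq = subsample_freq, n_rounds = n_rounds,
                 learning_rate = learning_rate, max_leaves = max_leaves,
                 min_child_samples = min_child_samples, mtry = mtry,
                 epochs = as.integer(epochs), hidden_size = hidden_size,
                 depth = depth, ffn_hidden = ffn_hidden,
                 aggregation = aggregation, encoder_sharing = encoder_sharing,
                 batch_size = batch_size, lr = lr,
                 radius = radius, n_bits = n_bits, seed = seed),
            class = "model_config")
}

is_traditional <- function(config) {
  grepl("_traditional$", config$family) || config$family == "oracle"
}

new_delta_model <- function(config, mode, fit, extra = list()) {
  structure(c(list(config = config, mode = mode, family = config$family,
                   fit = fit), extra),
            class = "delta_model")
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("<delta_model>: family %s (%s mode)\n", x$family, x$mode))
  invisible(x)
}

xgb_params <- function(config, n_train_molecules) {
  min_child <- if (n_train_molecules < 300) 5 else config$min_child_samples
  list(objective = "reg:squarederror",
       eta = config$learning_rate,
       tree_method = "hist", grow_policy = "lossguide",
       max_depth = 0, max_leaves = config$max_leaves,
       subsample = config$subsample_freq,
       min_child_weight = min_child,
       nthread = 1, seed = config$seed)
}

#' Train a traditional (single-molecule) property model
#'
#' Fits the absolute property from single-molecule features; pairwise
#' differences are later produced by subtracting two absolute predictions.
#'
#' @param records a `mol_dataset` (>= 2 molecules).
#' @param config a [model_config()] with a `*_traditional` family.
#' @return a `delta_model` in traditional mode (also supports
#'   [predict_value()]).
#' @export
train_traditional <- function(records, config = model_config("forest_traditional")) {
  stopifnot(inherits(config, "model_config"))
  if (!is_traditional(config) || config$family == "oracle")
    stop("`config$family` must be one of forest_traditional, gbm_traditional, graph_traditional")
  if (nrow(records) < 2) stop("need at least 2 training molecules")
  y <- records$value
  if (stats::sd(y) == 0)
    warning("constant training target; predictions will be constant")
  if (config$family == "graph_traditional")
    return(mpnn_train(records = records, pairs = NULL, config = config))
  fp <- morgan_fingerprints(records$smiles, config$radius, config$n_bits)
  fit <- switch(config$family,
    forest_traditional = {
      x <- as.matrix(fp)
      colnames(x) <- paste0("b", seq_len(ncol(x)))
      ranger::ranger(x = x, y = y, num.trees = config$n_trees,
                     mtry = config$mtry, seed = config$seed, num.threads = 1)
    },
    gbm_traditional = {
      dm <- xgboost::xgb.DMatrix(fp, label = y, nthread = 1)
      xgboost::xgb.train(params = xgb_params(config, nrow(records)),
                         data = dm, nrounds = config$n_rounds, verbose = 0)
    })
  new_delta_model(config, "traditional", fit)
}

#' Predict absolute property values for molecules
#'
#' @param model a traditional-mode `delta_model`.
#' @param smiles character vector of SMILES.
#' @return numeric vector of predicted values.
#' @export
predict_value <- function(model, smiles) {
  stopifnot(inherits(model, "delta_model"))
  if (model$mode != "traditional")
    stop("predict_value is only defined for traditional-mode models")
  if (model$family == "oracle") {
    can <- canonicalize_smiles(smiles)
    v <- model$fit$value[match(can, model$fit$smiles)]
    if (anyNA(v)) stop("oracle model has no value for some molecules")
    return(v)
  }
  if (model$family == "graph_traditional")
    return(mpnn_predict_values(model, smiles))
  fp <- morgan_fingerprints(smiles, model$config$radius, model$config$n_bits)
  switch(model$family,
    forest_traditional = {
      x <- as.matrix(fp)
      colnames(x) <- paste0("b", seq_len(ncol(x)))
      stats::predict(model$fit, data = x, num.threads = 1)$predictions
    },
    gbm_traditional = stats::predict(model$fit, xgboost::xgb.DMatrix(fp, nthread = 1)))
}

#' Pair differences from a traditional model by subtraction
#'
#' `prediction(second) - prediction(first)` for each ordered pair. Because
#' the two absolute predictions are deterministic per molecule, these
#' differences telescope exactly: self pairs give 0, swapped pairs negate,
#' and triplet additivity holds to floating precision.
#'
#' @param model a traditional-mode `delta_model`.
#' @param pairs a `pair_set`.
#' @return numeric vector of predicted differences, one per pair.
#' @export
predict_delta_by_subtraction <- function(model, pairs) {
  smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
  vals <- predict_value(model, smiles)
  names(vals) <- smiles
  unname(vals[pairs$smiles_2] - vals[pairs$smiles_1])
}

#' Train a delta model on concatenated fingerprints
#'
#' Gradient-boosted regression on ordered pairs: the feature vector is the
#' first molecule's fingerprint concatenated with the second's, and the
#' target is the observed property difference.
#'
#' @param pairs a training `pair_set`.
#' @param config a [model_config()] with family `gbm_delta`.
#' @return a `delta_model` in delta mode.
#' @export
train_delta_tabular <- function(pairs, config = model_config("gbm_delta")) {
  stopifnot(inherits(config, "model_config"), config$family == "gbm_delta",
            nrow(pairs) >= 1)
  if (stats::sd(pairs$delta) == 0)
    warning("all pair targets identical; model will be a constant predictor")
  smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
  fp <- morgan_fingerprints(smiles, config$radius, config$n_bits)
  rownames(fp) <- smiles
  X <- pair_feature_matrix(fp, match(pairs$smiles_1, smiles),
                           match(pairs$smiles_2, smiles))
  dm <- xgboost::xgb.DMatrix(X, label = pairs$delta, nthread = 1)
  fit <- xgboost::xgb.train(params = xgb_params(config, length(smiles)),
                            data = dm, nrounds = config$n_rounds, verbose = 0)
  new_delta_model(config, "delta", fit)
}

#' Train a two-encoder graph delta model
#'
#' Each molecule of a pair is encoded separately by a directed
#' message-passing network; the two latent vectors are concatenated and a
#' feed-forward head regresses the property difference. Encoders use
#' separate weights by default (`encoder_sharing = FALSE`).
#'
#' @param pairs a training `pair_set`.
#' @param config a [model_config()] with family `graph_delta`.
#' @return a `delta_model` in delta mode.
#' @export
train_delta_graph <- function(pairs, config = model_config("graph_delta")) {
  stopifnot(inherits(config, "model_config"), config$family == "graph_delta")
  mpnn_train(records = NULL, pairs = pairs, config = config)
}

#' Ground-truth oracle model
#'
#' A traditional-mode model whose absolute predictions are the recorded
#' values themselves. Injected into evaluation runs to validate the
#' plumbing: it must score r = 1 and MAE = 0 on every fold.
#'
#' @param records a `mol_dataset` covering every molecule the oracle will be
#'   asked about.
#' @return a `delta_model` with family `oracle`.
#' @export
oracle_model <- function(records) {
  new_delta_model(model_config("oracle"), "traditional",
                  fit = data.frame(smiles = records$smiles,
                                   value = records$value,
                                   stringsAsFactors = FALSE))
}

#' Predict property differences for ordered pairs
#'
#' The single prediction contract every trained model exposes. Traditional
#' models route through [predict_delta_by_subtraction()]; delta models
#' predict the difference directly from the paired representation.
#'
#' @param model a `delta_model`.
#' @param pairs a `pair_set` (columns `smiles_1`, `smiles_2`).
#' @return numeric vector, one finite prediction per pair, in input order.
#' @export
predict_delta <- function(model, pairs) {
  stopifnot(inherits(model, "delta_model"))
  if (nrow(pairs) == 0) return(numeric(0))
  if (model$mode == "traditional")
    return(predict_delta_by_subtraction(model, pairs))
  switch(model$family,
    gbm_delta = {
      cfg <- model$config
      smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
      fp <- morgan_fingerprints(smiles, cfg$radius, cfg$n_bits)
      X <- pair_feature_matrix(fp, match(pairs$smiles_1, smiles),
                               match(pairs$smiles_2, smiles))
      stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))
    },
    graph_delta = mpnn_predict_deltas(model, pairs),
    stop("unknown delta family: ", model$family))
}

#' Save a trained model bundle to disk
#'
#' Writes the configuration as JSON plus the fitted state, so a model can be
#' reloaded for prediction or invariant diagnostics.
#'
#' @param model a `delta_model`.
#' @param dir target directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(list(family = model$family, mode = model$mode,
                            config = unclass(cfg)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a saved model bundle
#'
#' @param dir directory written by [save_model()].
#' @return the `delta_model`.
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stop("no model bundle found at ", dir)
  readRDS(f)
}
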