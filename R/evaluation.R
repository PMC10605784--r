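# Cross-validated benchmarking and difference-centric analyses: regression
# metrics on pair differences, repeated-CV orchestration, scaffold
# stratification (same- vs different-scaffold pairs), error vs delta
# magnitude, and error vs chemical similarity.

#' Regression metrics for predicted differences
#'
#' Pearson's r, MAE, RMSE and sign accuracy (fraction of pairs whose
#' predicted difference has the same sign as the true one; pairs with a true
#' difference of exactly 0 carry no sign and are excluded, with the
#' exclusion count reported).
#'
#' @param true_deltas,pred_deltas equal-length numeric vectors.
#' @return a `metric_report` list: `pearson_r`, `mae`, `rmse`,
#'   `sign_accuracy`, `n_pairs`, `n_sign_excluded`.
#' @export
compute_metrics <- function(true_deltas, pred_deltas) {
  stopifnot(length(true_deltas) == length(pred_deltas),
            length(true_deltas) >= 1)
  err <- pred_deltas - true_deltas
  r <- if (stats::sd(true_deltas) == 0 || stats::sd(pred_deltas) == 0) {
    warning("zero variance; Pearson r undefined")
    NA_real_
  } else {
    stats::cor(true_deltas, pred_deltas)
  }
  nz <- true_deltas != 0
  sign_acc <- if (any(nz))
    mean(sign(pred_deltas[nz]) == sign(true_deltas[nz])) else NA_real_
  structure(list(pearson_r = r,
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 sign_accuracy = sign_acc,
                 n_pairs = length(true_deltas),
                 n_sign_excluded = sum(!nz)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report>: r = %.3f, MAE = %.3f, RMSE = %.3f, sign acc = %.3f (n = %d)\n",
              x$pearson_r, x$mae, x$rmse, x$sign_accuracy, x$n_pairs))
  invisible(x)
}

train_for_family <- function(cfg, train_records, train_pairs, dataset) {
  switch(cfg$family,
    oracle = oracle_model(dataset),
    forest_traditional = ,
    gbm_traditional = ,
    graph_traditional = train_traditional(train_records, cfg),
    gbm_delta = train_delta_tabular(train_pairs, cfg),
    graph_delta = train_delta_graph(train_pairs, cfg),
    stop("unknown family: ", cfg$family))
}

#' Repeated cross-validated benchmarking of model configurations
#'
#' For every configuration and every (repeat, fold) of the plan: train on
#' the fold's training molecules (traditional families) or training pairs
#' (delta families), predict the exhaustively cross-merged test pairs, and
#' score. Metrics are reported at three granularities: per fold, per repeat
#' (each repeat's test-pair predictions pooled across its folds), and a
#' summary of mean and SD over repeats. Test sets keep both orientations of
#' each unordered pair (and self pairs when enabled), so each unordered pair
#' contributes twice.
#'
#' @param dataset a `mol_dataset`.
#' @param configs named list of [model_config()] objects (names label the
#'   output rows).
#' @param plan a [make_fold_plan()] built from `dataset`.
#' @param include_self_pairs include self pairs in train and test pair sets
#'   (default `TRUE`).
#' @param keep_predictions keep per-pair predictions in the result (default
#'   `FALSE`; they can be large).
#' @return a `cv_result` list with data.frames `folds`, `repeats`,
#'   `summary`.
#' @export
run_cv <- function(dataset, configs, plan, include_self_pairs = TRUE,
                   keep_predictions = FALSE) {
  stopifnot(inherits(plan, "fold_plan"), length(configs) >= 1)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, function(c) c$family, character(1))
  fold_rows <- list(); rep_rows <- list(); preds <- list()
  for (label in names(configs)) {
    base_cfg <- configs[[label]]
    for (r in seq_len(plan$n_repeats)) {
      rep_true <- numeric(0); rep_pred <- numeric(0)
      for (f in seq_len(plan$n_folds)) {
        asg <- plan$assignment[[r]]
        test_ids <- names(asg)[asg == f]
        if (length(test_ids) < 2) {
          warning(sprintf("repeat %d fold %d: fewer than 2 test molecules; skipped", r, f))
          next
        }
        split <- pairs_for_fold(plan, r, f, dataset, include_self_pairs)
        cfg <- base_cfg
        cfg$seed <- derive_seed(base_cfg$seed, r * 1000 + f)
        train_records <- dataset[!(dataset$mol_id %in% test_ids), , drop = FALSE]
        model <- train_for_family(cfg, train_records, split$train, dataset)
        pred <- predict_delta(model, split$test)
        m <- suppressWarnings(compute_metrics(split$test$delta, pred))
        fold_rows[[length(fold_rows) + 1]] <- data.frame(
          config = label, family = base_cfg$family, repeat_ = r, fold = f,
          pearson_r = m$pearson_r, mae = m$mae, rmse = m$rmse,
          sign_accuracy = m$sign_accuracy, n_pairs = m$n_pairs,
          stringsAsFactors = FALSE)
        rep_true <- c(rep_true, split$test$delta)
        rep_pred <- c(rep_pred, pred)
        if (keep_predictions)
          preds[[length(preds) + 1]] <- data.frame(
            config = label, repeat_ = r, fold = f,
            first = split$test$first, second = split$test$second,
            smiles_1 = split$test$smiles_1, smiles_2 = split$test$smiles_2,
            true_delta = split$test$delta, pred_delta = pred,
            stringsAsFactors = FALSE)
      }
      m <- suppressWarnings(compute_metrics(rep_true, rep_pred))
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        config = label, family = base_cfg$family, repeat_ = r,
        pearson_r = m$pearson_r, mae = m$mae, rmse = m$rmse,
        sign_accuracy = m$sign_accuracy, n_pairs = m$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, fold_rows)
  repeats <- do.call(rbind, rep_rows)
  summary <- do.call(rbind, lapply(split(repeats, repeats$config), function(d) {
    data.frame(config = d$config[1], family = d$family[1],
               n_repeats = nrow(d),
               pearson_r_mean = mean(d$pearson_r), pearson_r_sd = stats::sd(d$pearson_r),
               mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               sign_accuracy_mean = mean(d$sign_accuracy),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(folds = folds, repeats = repeats, summary = summary,
                 predictions = if (keep_predictions) do.call(rbind, preds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(x$summary)
  invisible(x)
}

#' Paired comparison of two model configurations
#'
#' Compares repeat-level metric values of two configurations from one
#' [run_cv()] with a paired test. The default paired t-test assumes the
#' repeat-level differences are roughly normal (check with
#' `method = "ks"` first or use the Wilcoxon alternative); no automatic
#' selection is performed.
#'
#' @param cv a `cv_result`.
#' @param config_a,config_b configuration labels in `cv`.
#' @param metric one of "pearson_r", "mae", "rmse", "sign_accuracy".
#' @param method "t" (paired t-test), "wilcoxon" (paired signed-rank), or
#'   "ks" (Kolmogorov-Smirnov normality check of the paired differences
#'   against a fitted normal).
#' @return an `htest` object.
#' @export
compare_models <- function(cv, config_a, config_b, metric = "mae",
                           method = c("t", "wilcoxon", "ks")) {
  method <- match.arg(method)
  a <- cv$repeats[cv$repeats$config == config_a, ]
  b <- cv$repeats[cv$repeats$config == config_b, ]
  stopifnot(nrow(a) > 0, nrow(a) == nrow(b))
  x <- a[[metric]][order(a$repeat_)]
  y <- b[[metric]][order(b$repeat_)]
  switch(method,
    t = stats::t.test(x, y, paired = TRUE),
    wilcoxon = stats::wilcox.test(x, y, paired = TRUE, exact = FALSE),
    ks = {
      d <- x - y
      stats::ks.test(d, "pnorm", mean = mean(d), sd = stats::sd(d))
    })
}

#' Label pairs as same- or different-scaffold
#'
#' Computes the Bemis-Murcko scaffold of both molecules of every pair and
#' compares the scaffold strings. Acyclic molecules have the empty scaffold,
#' and two empty scaffolds compare as "same". The two groups partition the
#' pair set.
#'
#' @param pairs a `pair_set`.
#' @return the pairs with an added logical column `same_scaffold`.
#' @export
scaffold_partition <- function(pairs) {
  smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
  scaf <- murcko_scaffold(smiles)
  names(scaf) <- smiles
  out <- as.data.frame(pairs)
  out$same_scaffold <- scaf[pairs$smiles_1] == scaf[pairs$smiles_2]
  rownames(out) <- NULL
  out
}

#' Metrics stratified by scaffold relationship
#'
#' @param pairs a `pair_set`.
#' @param pred_deltas predictions aligned with `pairs`.
#' @return list with `metric_report`s `same_scaffold` and
#'   `different_scaffold` (NULL for an empty group) and the group sizes.
#' @export
scaffold_metrics <- function(pairs, pred_deltas) {
  lab <- scaffold_partition(pairs)
  same <- lab$same_scaffold
  mk <- function(sel) if (any(sel))
    suppressWarnings(compute_metrics(lab$delta[sel], pred_deltas[sel])) else NULL
  list(same_scaffold = mk(same), different_scaffold = mk(!same),
       n_same = sum(same), n_different = sum(!same))
}

#' Error analysis by difference magnitude
#'
#' Correlates the absolute prediction error with the absolute true
#' difference, and reports the MAE inside the top and bottom deciles of
#' `|true_delta|` (large differences are the pairs that matter most in
#' optimization campaigns and are systematically harder).
#'
#' @param true_deltas,pred_deltas equal-length numeric vectors (>= 10 pairs).
#' @param decile fraction defining the extreme groups (default 0.1). Ties at
#'   the decile boundary are broken by input position (stable sort), so both
#'   groups have exactly `floor(decile * n)` pairs.
#' @return list: `error_delta_r`, `top_decile_mae`, `bottom_decile_mae`,
#'   `n_per_decile`.
#' @export
magnitude_analysis <- function(true_deltas, pred_deltas, decile = 0.1) {
  n <- length(true_deltas)
  stopifnot(n >= 10, length(pred_deltas) == n, decile > 0, decile < 0.5)
  aerr <- abs(pred_deltas - true_deltas)
  amag <- abs(true_deltas)
  if (stats::sd(amag) == 0) warning("all |true_delta| equal; deciles degenerate")
  r <- if (stats::sd(aerr) == 0 || stats::sd(amag) == 0) NA_real_ else
    stats::cor(aerr, amag)
  k <- floor(decile * n)
  ord <- order(amag, seq_len(n))  # stable
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1, n)]
  list(error_delta_r = r,
       top_decile_mae = mean(aerr[top]),
       bottom_decile_mae = mean(aerr[bottom]),
       n_per_decile = k)
}

#' Per-pair similarity, error and difference table
#'
#' For each pair: the Tanimoto similarity of its two molecules, the absolute
#' prediction error and the true difference; plus the Pearson correlations
#' of similarity with error and with |true difference| (structurally similar
#' pairs tend to have small differences and small errors).
#'
#' @param pairs a `pair_set`.
#' @param pred_deltas predictions aligned with `pairs`.
#' @param radius,n_bits fingerprint parameters.
#' @return list with `table` (per-pair data.frame: `tanimoto`, `abs_error`,
#'   `true_delta`) and correlations `sim_error_r`, `sim_delta_r` (NA if a
#'   column is constant).
#' @export
similarity_analysis <- function(pairs, pred_deltas, radius = 2, n_bits = 2048) {
  stopifnot(nrow(pairs) == length(pred_deltas))
  smiles <- unique(c(pairs$smiles_1, pairs$smiles_2))
  fp <- morgan_fingerprints(smiles, radius, n_bits)
  f1 <- fp[match(pairs$smiles_1, smiles), , drop = FALSE]
  f2 <- fp[match(pairs$smiles_2, smiles), , drop = FALSE]
  inter <- Matrix::rowSums(f1 * f2)
  un <- Matrix::rowSums(f1) + Matrix::rowSums(f2) - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  tab <- data.frame(tanimoto = sim,
                    abs_error = abs(pred_deltas - pairs$delta),
                    true_delta = pairs$delta)
  safe_cor <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(table = tab,
       sim_error_r = safe_cor(tab$tanimoto, tab$abs_error),
       sim_delta_r = safe_cor(tab$tanimoto, abs(tab$true_delta)))
}
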