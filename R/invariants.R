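# Invariant diagnostics for pair-predicting models. A perfect difference
# predictor must (1) predict 0 for a molecule paired with itself,
# (2) negate its prediction when the pair order is swapped and
# (3) be additive over triplets: d(x,y) + d(y,z) = d(x,z).
# Traditional predict-then-subtract models satisfy all three exactly by
# construction (their differences telescope); direct delta models satisfy
# them only approximately, and the residuals are unsupervised measures of
# model quality that need no labels.

#' Mean absolute self-pair prediction (zero-difference residual)
#'
#' Mean of `|predict_delta(x, x)|` over molecules; exactly 0 for any
#' traditional model, and for a delta model a label-free measure of how well
#' it learned that identical molecules have no property difference.
#'
#' @param model a `delta_model`.
#' @param records a `mol_dataset` (>= 1 molecule).
#' @return non-negative scalar.
#' @export
self_difference_mae <- function(model, records) {
  stopifnot(nrow(records) >= 1)
  pairs <- new_pair_set(
    data.frame(first = records$mol_id, second = records$mol_id,
               smiles_1 = records$smiles, smiles_2 = records$smiles,
               delta = 0, stringsAsFactors = FALSE),
    include_self_pairs = TRUE, origin = "test")
  mean(abs(predict_delta(model, pairs)))
}

#' Swap correlation (antisymmetry diagnostic)
#'
#' Pearson correlation between predictions on ordered pairs and predictions
#' on the same pairs with the molecule order swapped. Exactly -1 for any
#' traditional model; near -1 for a well-behaved delta model. Self pairs
#' carry no swap information and are excluded.
#'
#' @param model a `delta_model`.
#' @param pairs a `pair_set` with at least 2 distinct non-self pairs.
#' @return correlation in `[-1, 1]`, or `NA` with a warning if predictions
#'   are constant.
#' @export
swap_correlation <- function(model, pairs) {
  pairs <- pairs[pairs$first != pairs$second, , drop = FALSE]
  if (nrow(pairs) < 2) stop("need at least 2 non-self pairs")
  swapped <- pairs
  swapped[, c("first", "second", "smiles_1", "smiles_2")] <-
    pairs[, c("second", "first", "smiles_2", "smiles_1")]
  swapped$delta <- -pairs$delta
  p_fwd <- predict_delta(model, pairs)
  p_rev <- predict_delta(model, swapped)
  if (stats::sd(p_fwd) == 0 || stats::sd(p_rev) == 0) {
    warning("constant predictions; swap correlation undefined")
    return(NA_real_)
  }
  stats::cor(p_fwd, p_rev)
}

# uniform sample of ordered triplets of distinct molecule indices
sample_triplets <- function(n, n_triplets, seed) {
  total <- n * (n - 1) * (n - 2)
  if (total <= n_triplets) {
    g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
    g <- g[g$x != g$y & g$y != g$z & g$x != g$z, c("x", "y", "z")]
    return(as.matrix(g))
  }
  with_seed(seed, {
    out <- matrix(0L, 0, 3)
    while (nrow(out) < n_triplets) {
      need <- n_triplets - nrow(out)
      cand <- matrix(sample.int(n, 3 * ceiling(need * 1.3), replace = TRUE),
                     ncol = 3)
      ok <- cand[, 1] != cand[, 2] & cand[, 2] != cand[, 3] & cand[, 1] != cand[, 3]
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n_triplets), , drop = FALSE]
  })
}

#' Triplet additivity residual
#'
#' Mean of `|d(x,y) + d(y,z) - d(x,z)|` over ordered triplets of distinct
#' molecules. Enumerates all `n (n - 1) (n - 2)` triplets when that count is
#' at most `max_triplets`, otherwise takes a seeded uniform sample. Exactly 0
#' (to floating precision) for traditional models.
#'
#' @param model a `delta_model`.
#' @param records a `mol_dataset` (>= 3 molecules).
#' @param max_triplets enumeration/sampling cap (default 1e5; the full count
#'   is cubic in molecules).
#' @param seed triplet-sampling seed.
#' @return non-negative scalar with attributes `n_triplets` and `exhaustive`.
#' @export
additivity_mae <- function(model, records, max_triplets = 1e5, seed = 1) {
  n <- nrow(records)
  stopifnot(n >= 3)
  tri <- sample_triplets(n, max_triplets, seed)
  # predict each needed ordered pair once
  pair_keys <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  uk <- unique(pair_keys)
  up <- new_pair_set(
    data.frame(first = records$mol_id[uk[, 1]], second = records$mol_id[uk[, 2]],
               smiles_1 = records$smiles[uk[, 1]], smiles_2 = records$smiles[uk[, 2]],
               delta = records$value[uk[, 2]] - records$value[uk[, 1]],
               stringsAsFactors = FALSE),
    include_self_pairs = FALSE, origin = "test")
  pred <- predict_delta(model, up)
  key <- function(m) paste(m[, 1], m[, 2])
  lut <- stats::setNames(pred, key(uk))
  p_xy <- lut[key(tri[, c(1, 2), drop = FALSE])]
  p_yz <- lut[key(tri[, c(2, 3), drop = FALSE])]
  p_xz <- lut[key(tri[, c(1, 3), drop = FALSE])]
  resid <- abs(p_xy + p_yz - p_xz)
  res <- mean(resid)
  attr(res, "n_triplets") <- nrow(tri)
  attr(res, "exhaustive") <- n * (n - 1) * (n - 2) <= max_triplets
  attr(res, "se") <- stats::sd(resid) / sqrt(length(resid))
  res
}

#' Full invariant report for a model
#'
#' Bundles the three diagnostics over one molecule set: self-pair MAE, swap
#' correlation (over all non-self ordered pairs of the set) and triplet
#' additivity MAE.
#'
#' @inheritParams additivity_mae
#' @return an `invariant_report` list: `self_mae`, `swap_r`,
#'   `additivity_mae`, `n_molecules`, `n_triplets_used`,
#'   `triplet_sampling_seed`.
#' @export
invariant_report <- function(model, records, max_triplets = 1e5, seed = 1) {
  pairs <- cross_merge(records, include_self_pairs = FALSE)
  amae <- additivity_mae(model, records, max_triplets, seed)
  structure(list(self_mae = self_difference_mae(model, records),
                 swap_r = swap_correlation(model, pairs),
                 additivity_mae = as.numeric(amae),
                 n_molecules = nrow(records),
                 n_triplets_used = attr(amae, "n_triplets"),
                 triplet_sampling_seed = seed),
            class = "invariant_report")
}

#' @export
print.invariant_report <- function(x, ...) {
  cat(sprintf(paste0("<invariant_report> (%d molecules)\n",
                     "  self-pair MAE : %.4g\n",
                     "  swap r        : %.4g\n",
                     "  additivity MAE: %.4g (%d triplets)\n"),
              x$n_molecules, x$self_mae, x$swap_r, x$additivity_mae,
              x$n_triplets_used))
  invisible(x)
}

#' Write an invariant report as JSON
#'
#' @param report an `invariant_report`.
#' @param path output path.
#' @export
invariant_report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Correlate an unsupervised diagnostic with supervised performance
#'
#' Pearson correlation across datasets between an invariant metric (e.g.
#' self-pair MAE) and a cross-validation metric (e.g. CV MAE). A strong
#' correlation means the label-free diagnostic anticipates how well the
#' model will do.
#'
#' @param rows data.frame whose first column is the invariant metric and
#'   second column the CV metric (>= 3 rows).
#' @return Pearson correlation.
#' @export
anticipate_performance <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) < 3) stop("need at least 3 datasets to correlate")
  stats::cor(rows[[1]], rows[[2]])
}
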