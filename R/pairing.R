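# Ordered pair construction and molecule-level cross-validation folds.
# Splitting happens on molecules BEFORE pairing, so no molecule can
# contribute pairs to both the training and the test side of a fold: pairs
# of (train, test) molecules are simply never formed.

#' Exhaustively cross-merge a molecule set into ordered pairs
#'
#' Builds every ordered pair of distinct molecules (and, by default, every
#' self pair) with the ground-truth difference `value(second) - value(first)`.
#' Order matters: (a, b) and (b, a) are distinct pairs whose targets are
#' exact negations. Pair order is deterministic (lexicographic by mol_id).
#'
#' @param records a `mol_dataset` (or data.frame with `mol_id`, `smiles`,
#'   `value`).
#' @param include_self_pairs include (x, x) pairs with target 0 (default
#'   `TRUE`; self pairs anchor the zero-difference invariant during training).
#' @return a `pair_set`: data.frame with `first`, `second`, `smiles_1`,
#'   `smiles_2`, `delta`; `n^2` rows with self pairs, `n (n - 1)` without.
#' @export
cross_merge <- function(records, include_self_pairs = TRUE) {
  stopifnot(all(c("mol_id", "smiles", "value") %in% names(records)))
  if (anyDuplicated(records$mol_id)) stop("mol_id values must be distinct")
  n <- nrow(records)
  if (n < 2 && !include_self_pairs)
    stop("need at least 2 molecules to form non-self pairs")
  ord <- order(records$mol_id)
  records <- records[ord, , drop = FALSE]
  idx <- expand.grid(second = seq_len(n), first = seq_len(n))  # first varies slowest
  if (!include_self_pairs) idx <- idx[idx$first != idx$second, , drop = FALSE]
  pairs <- data.frame(
    first = records$mol_id[idx$first],
    second = records$mol_id[idx$second],
    smiles_1 = records$smiles[idx$first],
    smiles_2 = records$smiles[idx$second],
    delta = records$value[idx$second] - records$value[idx$first],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new_pair_set(pairs, include_self_pairs = include_self_pairs)
}

new_pair_set <- function(df, include_self_pairs, origin = "train") {
  structure(df, include_self_pairs = include_self_pairs, origin = origin,
            class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set>: %d ordered pairs (%d molecules, self pairs %s)\n",
              nrow(x), length(unique(c(x$first, x$second))),
              if (isTRUE(attr(x, "include_self_pairs"))) "on" else "off"))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Build a repeated k-fold plan over molecules
#'
#' Random molecule-level partition for each repeat; fold sizes differ by at
#' most one. Each repeat shuffles with its own sub-seed derived from the
#' master seed, so any (repeat, fold) split is reconstructible in isolation.
#'
#' @param records a `mol_dataset`.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats independent repeats (default 5).
#' @param seed master seed.
#' @return a `fold_plan`: list with `n_folds`, `n_repeats`, `seed`, and
#'   `assignment` (per repeat, a named integer vector mol_id -> fold).
#' @export
make_fold_plan <- function(records, n_folds = 10, n_repeats = 5, seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  ids <- sort(records$mol_id)
  n <- length(ids)
  if (n_folds > n) stop("more folds (", n_folds, ") than molecules (", n, ")")
  assignment <- lapply(seq_len(n_repeats), function(r) {
    sub_seed <- derive_seed(seed, r)
    with_seed(sub_seed, {
      perm <- sample.int(n)
      folds <- integer(n)
      folds[perm] <- rep(seq_len(n_folds), length.out = n)
      stats::setNames(folds, ids)
    })
  })
  structure(list(n_folds = n_folds, n_repeats = n_repeats, seed = seed,
                 assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan>: %d repeats x %d folds over %d molecules (seed %d)\n",
              x$n_repeats, x$n_folds, length(x$assignment[[1]]), x$seed))
  invisible(x)
}

#' Train/test pair sets for one fold of a plan
#'
#' Training pairs are cross-merged only from molecules outside the fold and
#' test pairs only from molecules inside it, so the two molecule sets are
#' disjoint by construction (the leakage firewall).
#'
#' @param plan a [make_fold_plan()] result.
#' @param repeat_ repeat index in `1..n_repeats`.
#' @param fold fold index in `1..n_folds`.
#' @param records the `mol_dataset` the plan was built from.
#' @param include_self_pairs passed to [cross_merge()].
#' @return list with elements `train` and `test` (both `pair_set`).
#' @export
pairs_for_fold <- function(plan, repeat_, fold, records, include_self_pairs = TRUE) {
  stopifnot(inherits(plan, "fold_plan"),
            repeat_ >= 1, repeat_ <= plan$n_repeats,
            fold >= 1, fold <= plan$n_folds)
  asg <- plan$assignment[[repeat_]]
  if (!setequal(names(asg), records$mol_id))
    stop("fold plan was built from a different molecule set")
  test_ids <- names(asg)[asg == fold]
  train <- cross_merge(records[!(records$mol_id %in% test_ids), , drop = FALSE],
                       include_self_pairs)
  test <- cross_merge(records[records$mol_id %in% test_ids, , drop = FALSE],
                      include_self_pairs)
  attr(train, "origin") <- "train"
  attr(test, "origin") <- "test"
  list(train = train, test = test)
}

#' Check that two pair sets share no molecules
#'
#' @param train,test `pair_set` objects.
#' @return `TRUE` iff the molecule sets underlying the two pair sets are
#'   disjoint.
#' @export
leakage_check <- function(train, test) {
  a <- unique(c(train$first, train$second))
  b <- unique(c(test$first, test$second))
  length(intersect(a, b)) == 0
}

#' Write a pair set as CSV
#'
#' @param pairs a `pair_set`.
#' @param path output path; columns `smiles_1`, `smiles_2`, `delta`.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs)[, c("smiles_1", "smiles_2", "delta")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fold plan to JSON
#'
#' @param plan a `fold_plan`.
#' @param path output JSON path.
#' @export
fold_plan_to_json <- function(plan, path) {
  jsonlite::write_json(
    list(n_folds = plan$n_folds, n_repeats = plan$n_repeats, seed = plan$seed,
         assignment = lapply(plan$assignment, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
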