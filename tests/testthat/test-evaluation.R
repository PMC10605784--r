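test_that("metric arithmetic matches hand-computed values", {
  m <- compute_metrics(c(1, 2), c(2, 4))
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5))
  perfect <- compute_metrics(c(-1, 0.5, 2), c(-1, 0.5, 2))
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$sign_accuracy, 1)
  anti <- compute_metrics(c(1, -2, 3), c(-1, 2, -3))
  expect_equal(anti$pearson_r, -1)
  expect_equal(anti$sign_accuracy, 0)
  expect_warning(z <- compute_metrics(c(1, 1), c(1, 2)), "zero variance")
  expect_true(is.na(z$pearson_r))
  expect_equal(z$mae, 0.5)
})

test_that("sign accuracy excludes exact-zero true differences", {
  m <- compute_metrics(c(0, 0, 1, -1), c(1, -5, 2, 1))
  expect_equal(m$n_sign_excluded, 2)
  expect_equal(m$sign_accuracy, 0.5)
})

test_that("RMSE is never below MAE", {
  set.seed(3)
  for (i in 1:25) {
    tr <- rnorm(40); pr <- tr + rnorm(40, sd = runif(1, 0, 2))
    m <- compute_metrics(tr, pr)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("the oracle scores perfectly on every fold of a repeated CV", {
  ds <- synth_ds(40, seed = 71)
  plan <- make_fold_plan(ds, n_folds = 4, n_repeats = 2, seed = 7)
  cv <- run_cv(ds, list(oracle = model_config("oracle")), plan)
  expect_equal(nrow(cv$folds), 8)
  expect_equal(cv$folds$pearson_r, rep(1, 8), tolerance = 1e-12)
  expect_equal(cv$folds$mae, rep(0, 8), tolerance = 1e-12)
  expect_equal(cv$folds$sign_accuracy, rep(1, 8))
  expect_equal(cv$summary$mae_mean, 0, tolerance = 1e-12)
  expect_equal(cv$summary$pearson_r_sd, 0, tolerance = 1e-12)
})

test_that("a full 5x10 plan yields 50 fold-level reports per configuration", {
  ds <- synth_ds(60, seed = 81)
  plan <- make_fold_plan(ds, n_folds = 10, n_repeats = 5, seed = 2)
  cv <- run_cv(ds, list(oracle = model_config("oracle")), plan)
  expect_equal(nrow(cv$folds), 50)
  expect_equal(nrow(cv$repeats), 5)
  expect_equal(cv$summary$n_repeats, 5)
})

test_that("model comparison runs paired tests over repeat-level metrics", {
  ds <- synth_ds(40, seed = 71)
  plan <- make_fold_plan(ds, n_folds = 3, n_repeats = 3, seed = 5)
  cv <- run_cv(ds, list(forest = model_config("forest_traditional", seed = 1),
                        gbm = model_config("gbm_traditional", seed = 1)), plan)
  tt <- compare_models(cv, "forest", "gbm", metric = "mae", method = "t")
  expect_s3_class(tt, "htest")
  wt <- compare_models(cv, "forest", "gbm", metric = "mae", method = "wilcoxon")
  expect_s3_class(wt, "htest")
  ks <- compare_models(cv, "forest", "gbm", metric = "mae", method = "ks")
  expect_s3_class(ks, "htest")
})

test_that("scaffold partitioning labels pairs by Bemis-Murcko equality", {
  rec <- data.frame(
    mol_id = c("tol", "etb", "pyr", "hex", "oct"),
    smiles = canonicalize_smiles(c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1C",
                                   "CCCCCC", "CCCCCCCC")),
    value = 1:5, stringsAsFactors = FALSE)
  p <- cross_merge(rec, include_self_pairs = FALSE)
  lab <- scaffold_partition(p)
  get <- function(a, b) lab$same_scaffold[lab$first == a & lab$second == b]
  expect_true(get("tol", "etb"))     # both benzene scaffolds
  expect_false(get("tol", "pyr"))    # benzene vs pyridine
  expect_true(get("hex", "oct"))     # two acyclic molecules: empty == empty
  expect_equal(sum(lab$same_scaffold) + sum(!lab$same_scaffold), nrow(p))
  sm <- scaffold_metrics(p, p$delta)
  expect_equal(sm$n_same + sm$n_different, nrow(p))
  expect_equal(sm$same_scaffold$mae, 0)
})

test_that("magnitude analysis isolates the extreme deciles", {
  set.seed(11)
  tr <- rnorm(100)
  mag <- suppressWarnings(magnitude_analysis(tr, tr))
  expect_equal(mag$n_per_decile, 10)
  expect_equal(mag$top_decile_mae, 0)
  expect_equal(mag$bottom_decile_mae, 0)
  expect_true(is.na(mag$error_delta_r))
  # errors proportional to |true|: correlation exactly 1
  tr20 <- seq(-2, 2, length.out = 20)
  pred <- tr20 + 0.1 * abs(tr20)
  mag2 <- magnitude_analysis(tr20, pred)
  expect_equal(mag2$error_delta_r, 1, tolerance = 1e-12)
  expect_gt(mag2$top_decile_mae, mag2$bottom_decile_mae)
  expect_error(magnitude_analysis(1:5, 1:5), "n >= 10")
})

test_that("similarity analysis tabulates tanimoto against error and delta", {
  ds <- synth_ds(20, seed = 33)
  p <- cross_merge(ds[1:8, ])
  out <- similarity_analysis(p, p$delta)  # perfect predictions
  expect_equal(nrow(out$table), nrow(p))
  selfrows <- p$first == p$second
  expect_equal(out$table$tanimoto[selfrows], rep(1, sum(selfrows)))
  expect_equal(out$table$true_delta[selfrows], rep(0, sum(selfrows)))
  expect_true(is.na(out$sim_error_r))    # all errors zero -> constant column
  expect_true(is.finite(out$sim_delta_r))
})
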