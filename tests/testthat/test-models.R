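test_that("traditional models fit, predict finitely, and are seed-deterministic", {
  ds <- synth_ds(50)
  for (fam in c("forest_traditional", "gbm_traditional")) {
    m1 <- train_traditional(ds, model_config(fam, seed = 5))
    v1 <- predict_value(m1, ds$smiles[1:5])
    expect_true(all(is.finite(v1)))
    m2 <- train_traditional(ds, model_config(fam, seed = 5))
    expect_identical(v1, predict_value(m2, ds$smiles[1:5]))
  }
  expect_error(train_traditional(ds[1, , drop = FALSE],
                                 model_config("forest_traditional")), "at least 2")
  dconst <- ds[1:5, , drop = FALSE]
  dconst$value <- 1
  expect_warning(train_traditional(dconst, model_config("gbm_traditional")),
                 "constant")
})

test_that("subtraction-based deltas telescope exactly", {
  m <- trad_forest()
  ds <- synth_ds(50)
  pairs <- cross_merge(ds[1:12, ])
  pred <- predict_delta_by_subtraction(m, pairs)
  # self pairs exactly zero
  expect_identical(pred[pairs$first == pairs$second], rep(0, 12))
  # swapped pairs exactly negate
  key <- paste(pairs$first, pairs$second)
  swapped <- pred[match(paste(pairs$second, pairs$first), key)]
  expect_identical(pred + swapped, rep(0, length(pred)))
  # triplet additivity to floating precision
  lut <- setNames(pred, key)
  ids <- unique(pairs$first)[1:6]
  tri <- expand.grid(a = ids, b = ids, c = ids, stringsAsFactors = FALSE)
  expect_equal(lut[paste(tri$a, tri$b)] + lut[paste(tri$b, tri$c)],
               setNames(lut[paste(tri$a, tri$c)], paste(tri$a, tri$b)),
               tolerance = 1e-12)
  # the generic routes traditional models through subtraction
  expect_identical(predict_delta(m, pairs), pred)
})

test_that("the oracle model reproduces ground-truth differences", {
  ds <- synth_ds(20, seed = 33)
  o <- oracle_model(ds)
  p <- cross_merge(ds)
  expect_equal(predict_delta(o, p), p$delta, tolerance = 1e-12)
})

test_that("delta gradient boosting fits pairs and is deterministic", {
  ds <- synth_ds(50)
  p <- cross_merge(ds[1:3, ])
  expect_equal(nrow(p), 9)
  m <- train_delta_tabular(p, model_config("gbm_delta", seed = 3))
  pred <- predict_delta(m, p)
  expect_length(pred, 9)
  expect_true(all(is.finite(pred)))
  m2 <- train_delta_tabular(p, model_config("gbm_delta", seed = 3))
  expect_identical(pred, predict_delta(m2, p))
  expect_warning(train_delta_tabular(
    {q <- p; q$delta <- 0; q}, model_config("gbm_delta")), "identical")
})

test_that("adding a constant to training values barely moves forest deltas", {
  ds <- synth_ds(50)
  ds5 <- ds; ds5$value <- ds$value + 5
  pairs <- cross_merge(ds[1:10, ])
  d0 <- predict_delta(train_traditional(ds, model_config("forest_traditional", seed = 5)), pairs)
  d5 <- predict_delta(train_traditional(ds5, model_config("forest_traditional", seed = 5)), pairs)
  expect_lte(max(abs(d0 - d5)), 0.1 * sd(ds$value))
})

test_that("model bundles save and load with identical predictions", {
  m <- trad_gbm()
  ds <- synth_ds(50)
  pairs <- cross_merge(ds[1:5, ])
  dir <- file.path(tempdir(), "bundle_gbm")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict_delta(m, pairs), predict_delta(m2, pairs))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$family, "gbm_traditional")
  expect_error(load_model(file.path(tempdir(), "nope")), "no model bundle")
})
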