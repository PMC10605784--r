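test_that("cross-merge pair counts match the closed forms n^2 and n(n-1)", {
  for (n in c(2, 3, 7, 25, 50, 120, 200)) {
    rec <- fake_records(n)
    expect_equal(nrow(cross_merge(rec, include_self_pairs = TRUE)), n^2)
    expect_equal(nrow(cross_merge(rec, include_self_pairs = FALSE)), n * (n - 1))
  }
  expect_error(cross_merge(fake_records(1), include_self_pairs = FALSE),
               "at least 2")
})

test_that("ground-truth deltas are antisymmetric, zero on self pairs, and additive", {
  rec <- fake_records(15, seed = 4)
  p <- cross_merge(rec, include_self_pairs = TRUE)
  expect_equal(p$delta[p$first == p$second], rep(0, 15))
  key <- paste(p$first, p$second)
  swapped <- p$delta[match(paste(p$second, p$first), key)]
  expect_identical(p$delta + swapped, rep(0, nrow(p)))
  # additivity telescopes exactly: d(a,b) + d(b,c) = d(a,c)
  lut <- setNames(p$delta, key)
  ids <- rec$mol_id
  tri <- expand.grid(a = ids[1:6], b = ids[1:6], c = ids[1:6],
                     stringsAsFactors = FALSE)
  expect_identical(
    lut[paste(tri$a, tri$b)] + lut[paste(tri$b, tri$c)],
    setNames(lut[paste(tri$a, tri$c)], paste(tri$a, tri$b)))
})

test_that("pair ordering is deterministic and lexicographic in mol_id", {
  rec <- fake_records(5)[c(3, 1, 5, 2, 4), ]
  p1 <- cross_merge(rec)
  p2 <- cross_merge(rec[sample(5), ])
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_false(is.unsorted(p1$first))
})

test_that("fold plans partition molecules with near-equal sizes, reproducibly", {
  rec <- fake_records(103)
  plan <- make_fold_plan(rec, n_folds = 10, n_repeats = 3, seed = 42)
  for (r in 1:3) {
    asg <- plan$assignment[[r]]
    expect_setequal(names(asg), rec$mol_id)
    sizes <- table(asg)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(sum(sizes), 103)
  }
  plan2 <- make_fold_plan(rec, n_folds = 10, n_repeats = 3, seed = 42)
  expect_identical(plan$assignment, plan2$assignment)
  expect_false(identical(plan$assignment[[1]], plan$assignment[[2]]))
  expect_error(make_fold_plan(fake_records(5), n_folds = 10), "more folds")
})

test_that("fold pair sets are leak-free with the expected counts", {
  rec <- fake_records(100)
  plan <- make_fold_plan(rec, n_folds = 10, n_repeats = 1, seed = 9)
  test_union <- character(0)
  for (f in 1:10) {
    split <- pairs_for_fold(plan, 1, f, rec)
    expect_true(leakage_check(split$train, split$test))
    expect_equal(nrow(split$train), 8100)
    expect_equal(nrow(split$test), 100)
    test_union <- c(test_union, unique(split$test$first))
  }
  expect_setequal(test_union, rec$mol_id)
})

test_that("leakage_check detects sharing and accepts empty sets", {
  rec <- fake_records(6)
  a <- cross_merge(rec[1:3, ]); b <- cross_merge(rec[4:6, ])
  expect_true(leakage_check(a, b))
  expect_false(leakage_check(a, cross_merge(rec[3:5, ])))
  expect_true(leakage_check(a, b[0, , drop = FALSE]))
})

test_that("pair sets and fold plans serialize to CSV / JSON", {
  ds <- synth_ds(10, seed = 33)
  p <- cross_merge(ds)
  f <- file.path(tempdir(), "pairs.csv")
  write_pairs(p, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_named(back, c("smiles_1", "smiles_2", "delta"))
  expect_equal(nrow(back), 100)
  plan <- make_fold_plan(ds, n_folds = 3, n_repeats = 2, seed = 1)
  j <- file.path(tempdir(), "plan.json")
  fold_plan_to_json(plan, j)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$n_folds, 3)
  expect_length(parsed$assignment, 2)
})
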