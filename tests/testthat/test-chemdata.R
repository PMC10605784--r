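test_that("parse_table removes qualifier and invalid rows with provenance counts", {
  raw <- data.frame(
    smiles_text = c("CCO", "CCO", "C(C", "CCN", "c1ccccc1"),
    value_text = c("0.5", ">10", "1.0", "<2", "3e-1"),
    source_row = 1:5, stringsAsFactors = FALSE)
  kept <- parse_table(raw)
  prov <- attr(kept, "provenance")
  expect_equal(kept$smiles_text, c("CCO", "c1ccccc1"))
  expect_equal(prov$qualifier, 2)
  expect_equal(prov$invalid_smiles, 1)
  expect_error(
    parse_table(data.frame(smiles_text = "C(C", value_text = "1",
                           source_row = 1)),
    "no usable rows")
})

test_that("canonicalization merges notations and is idempotent", {
  can <- canonicalize_smiles(c("OCC", "CCO"))
  expect_equal(can[1], can[2])
  benzene <- canonicalize_smiles("c1ccccc1")
  expect_length(benzene, 1)
  expect_equal(canonicalize_smiles(can[1]), can[1])
  expect_equal(canonicalize_smiles(benzene), benzene)
  expect_error(canonicalize_smiles("C(C"), "C\\(C")
})

test_that("value transforms follow the log10 / identity contract", {
  expect_equal(apply_transform(100, transform_spec("log10")), 2)
  expect_equal(apply_transform(0, transform_spec("log10", pre_offset = 1)), 0)
  expect_equal(apply_transform(-3.2, transform_spec("identity")), -3.2)
  expect_error(apply_transform(c(1, 0), transform_spec("log10")), "rows: 2")
  expect_error(transform_spec("identity", pre_offset = 1))
  expect_error(transform_spec("log10", pre_offset = -1))
  # log10 with zero offset inverts 10^x
  x <- seq(-3, 3, length.out = 31)
  expect_equal(apply_transform(10^x, transform_spec("log10")), x,
               tolerance = 1e-12)
})

test_that("value parsing accepts decimal and scientific notation", {
  raw <- data.frame(smiles_text = c("CCO", "CCN", "CCC"),
                    value_text = c("1.5", "2e3", "1E-2"),
                    source_row = 1:3, stringsAsFactors = FALSE)
  kept <- parse_table(raw)
  expect_equal(nrow(kept), 3)
  ds <- curate_dataset(raw[1:2, ], transform = transform_spec("log10"))
  expect_equal(ds$value, c(log10(1.5), log10(2000)))
})

test_that("curation dedups on canonical structure (first kept) and is deterministic", {
  raw <- data.frame(
    smiles_text = c("CCO", "OCC", "CCN", "c1ccccc1"),
    value_text = c("1.0", "2.0", "3.0", "4.0"),
    source_row = 1:4, stringsAsFactors = FALSE)
  ds1 <- curate_dataset(raw, name = "d")
  expect_equal(nrow(ds1), 3)
  expect_equal(ds1$value[ds1$smiles == canonicalize_smiles("CCO")], 1.0)
  expect_equal(attr(ds1, "provenance")$duplicate_structure, 1)
  ds2 <- curate_dataset(raw, name = "d")
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  expect_identical(attr(ds1, "provenance"), attr(ds2, "provenance"))
})

test_that("user substitution tables replace SMILES before filtering", {
  raw <- data.frame(smiles_text = c("BADAMINE", "CCO"),
                    value_text = c("1", "2"), source_row = 1:2,
                    stringsAsFactors = FALSE)
  subs <- data.frame(from = "BADAMINE", to = "CCN", stringsAsFactors = FALSE)
  ds <- curate_dataset(raw, substitutions = subs)
  expect_equal(nrow(ds), 2)
  expect_true(canonicalize_smiles("CCN") %in% ds$smiles)
})

test_that("reference deduplication removes identical structures at threshold 1", {
  a <- curate_dataset(data.frame(
    smiles_text = c("CCO", "CCN", "c1ccccc1O"), value_text = c("1", "2", "3"),
    source_row = 1:3, stringsAsFactors = FALSE), name = "cand")
  ref <- curate_dataset(data.frame(
    smiles_text = c("OCC", "c1ccccc1"), value_text = c("9", "8"),
    source_row = 1:2, stringsAsFactors = FALSE), name = "ref")
  out <- dedup_against(a, ref, threshold = 1.0)
  # ethanol is in the reference (as OCC); phenol/aminoethane are similar but
  # not identical and must survive a threshold of exactly 1
  expect_equal(nrow(out), 2)
  expect_false(canonicalize_smiles("CCO") %in% out$smiles)
  expect_equal(attr(out, "provenance")$dedup_against_reference, 1)
  # self-dedup at threshold 1 removes everything (self-similarity is 1)
  expect_equal(nrow(dedup_against(a, a, 1.0)), 0)
  # empty-reference behaviour: candidates unchanged
  tiny <- ref[0, , drop = FALSE]
  expect_equal(nrow(dedup_against(a, tiny, 1.0)), 3)
})

test_that("dataset round-trips to CSV with a JSON provenance log", {
  ds <- synth_ds(20, seed = 33)
  tmp <- file.path(tempdir(), "ds.csv")
  paths <- write_dataset(ds, tmp)
  expect_true(file.exists(paths["csv"]))
  expect_true(file.exists(paths["provenance"]))
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$smiles, ds$smiles)
  expect_equal(back$value, ds$value)
  prov <- jsonlite::read_json(paths[["provenance"]])
  expect_equal(prov$n_molecules, 20)
})
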