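# Command-line entry points and run manifests. The CLI is a thin layer over
# the package functions: machine outputs go to files, log messages to
# stderr, and every run writes a manifest recording configuration, seeds and
# input digests so deterministic stages can be reproduced exactly.

#' Build a run manifest
#'
#' @param stage stage name (e.g. "cv").
#' @param config named list of effective options.
#' @param inputs character vector of input file paths (digested with MD5).
#' @return a list describing the run.
#' @export
run_manifest <- function(stage, config = list(), inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(stage = stage,
       package = "deltamol",
       version = as.character(utils::packageVersion("deltamol")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config,
       input_digests = digests)
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# read a curated dataset CSV back (columns smiles, value; mol_id optional)
mol_dataset_from_csv <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "value") %in% names(df)))
  if (!"mol_id" %in% names(df)) df$mol_id <- sprintf("m%05d", seq_len(nrow(df)))
  new_mol_dataset(df[, c("mol_id", "smiles", "value")], name = name,
                  transform = transform_spec("identity"))
}

cli_log <- function(...) message("[deltamol] ", ...)

parse_cli_flags <- function(args) {
  flags <- list(); positional <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        flags[[key]] <- TRUE; i <- i + 1
      } else {
        flags[[key]] <- args[i + 1]; i <- i + 2
      }
    } else {
      positional <- c(positional, a); i <- i + 1
    }
  }
  list(flags = flags, positional = positional)
}

flag_num <- function(flags, key, default) as.numeric(flags[[key]] %||% default)
flag_chr <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) default else as.character(v)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `generate`, `curate`, `pair`, `cv`, `train`,
#' `predict`, `invariants`, `report`. Intended to be called from a thin
#' Rscript wrapper (see `inst/cli/deltamol.R`); returns an exit status
#' instead of quitting so it is testable in-process.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cli_log("usage: deltamol <generate|curate|pair|cv|train|predict|invariants|report> [--flags]")
    return(2L)
  }
  cmd <- args[1]
  parsed <- parse_cli_flags(args[-1])
  fl <- parsed$flags
  status <- tryCatch({
    switch(cmd,
      generate = cli_generate(fl),
      curate = cli_curate(fl),
      pair = cli_pair(fl),
      cv = cli_cv(fl),
      train = cli_train(fl),
      predict = cli_predict(fl),
      invariants = cli_invariants(fl),
      report = cli_report(fl),
      { cli_log("unknown subcommand: ", cmd); 2L })
  }, error = function(e) {
    cli_log("error: ", conditionMessage(e))
    1L
  })
  as.integer(status %||% 0L)
}

cli_generate <- function(fl) {
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  cfg <- generator_config(n_molecules = flag_num(fl, "n", 600),
                          noise_sd = flag_num(fl, "noise-sd", 0.1),
                          assay_offset = flag_num(fl, "assay-offset", 0),
                          seed = flag_num(fl, "seed", 1))
  ds <- generate_library(cfg)
  utils::write.csv(data.frame(smiles = ds$smiles, value = ds$value),
                   out, row.names = FALSE)
  write_manifest(run_manifest("generate", config = list(
    n = cfg$n_molecules, noise_sd = cfg$noise_sd,
    assay_offset = cfg$assay_offset, seed = cfg$seed, out = out)),
    paste0(out, ".manifest.json"))
  cli_log("wrote ", nrow(ds), " molecules to ", out)
  0L
}

cli_curate <- function(fl) {
  input <- flag_chr(fl, "in") %||% stop("--in is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  raw <- read_property_table(input,
                             smiles_col = flag_chr(fl, "smiles-col", "smiles"),
                             value_col = flag_chr(fl, "value-col", "value"))
  spec <- transform_spec(flag_chr(fl, "transform", "identity"),
                         pre_offset = flag_num(fl, "pre-offset", 0))
  ds <- curate_dataset(raw, name = flag_chr(fl, "name", basename(input)),
                       transform = spec)
  paths <- write_dataset(ds, out)
  write_manifest(run_manifest("curate",
                              config = c(fl, list(out = out)), inputs = input),
                 paste0(out, ".manifest.json"))
  cli_log("curated ", nrow(ds), " molecules; provenance at ", paths["provenance"])
  0L
}

cli_pair <- function(fl) {
  input <- flag_chr(fl, "in") %||% stop("--in is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  ds <- mol_dataset_from_csv(input)
  pairs <- cross_merge(ds, include_self_pairs = !isTRUE(fl[["no-self-pairs"]]))
  write_pairs(pairs, out)
  write_manifest(run_manifest("pair", config = fl, inputs = input),
                 paste0(out, ".manifest.json"))
  cli_log("wrote ", nrow(pairs), " ordered pairs to ", out)
  0L
}

cli_cv <- function(fl) {
  input <- flag_chr(fl, "in") %||% stop("--in is required")
  prefix <- flag_chr(fl, "out-prefix") %||% stop("--out-prefix is required")
  seed <- flag_num(fl, "seed", 1)
  families <- strsplit(flag_chr(fl, "families", "gbm_delta"), ",")[[1]]
  ds <- mol_dataset_from_csv(input)
  plan <- make_fold_plan(ds, n_folds = flag_num(fl, "folds", 10),
                         n_repeats = flag_num(fl, "repeats", 5), seed = seed)
  configs <- stats::setNames(
    lapply(families, function(f) model_config(f, seed = seed)), families)
  cv <- run_cv(ds, configs, plan)
  utils::write.csv(cv$summary, paste0(prefix, "_summary.csv"), row.names = FALSE)
  utils::write.csv(cv$repeats, paste0(prefix, "_repeats.csv"), row.names = FALSE)
  utils::write.csv(cv$folds, paste0(prefix, "_folds.csv"), row.names = FALSE)
  write_manifest(run_manifest("cv", config = c(fl, list(seed = seed)),
                              inputs = input),
                 paste0(prefix, "_manifest.json"))
  cli_log("cross-validation finished; summary at ", prefix, "_summary.csv")
  0L
}

cli_train <- function(fl) {
  input <- flag_chr(fl, "in") %||% stop("--in is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  family <- flag_chr(fl, "family", "gbm_delta")
  cfg <- model_config(family, seed = flag_num(fl, "seed", 1))
  ds <- mol_dataset_from_csv(input)
  model <- if (is_traditional(cfg)) train_traditional(ds, cfg)
           else train_for_family(cfg, ds, cross_merge(ds), ds)
  save_model(model, out)
  write_manifest(run_manifest("train", config = fl, inputs = input),
                 file.path(out, "manifest.json"))
  cli_log("trained ", family, "; bundle at ", out)
  0L
}

cli_predict <- function(fl) {
  bundle <- flag_chr(fl, "model") %||% stop("--model is required")
  pairs_csv <- flag_chr(fl, "pairs") %||% stop("--pairs is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  model <- load_model(bundle)
  df <- utils::read.csv(pairs_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("smiles_1", "smiles_2") %in% names(df)))
  pairs <- new_pair_set(
    data.frame(first = df$smiles_1, second = df$smiles_2,
               smiles_1 = canonicalize_smiles(df$smiles_1),
               smiles_2 = canonicalize_smiles(df$smiles_2),
               delta = if ("delta" %in% names(df)) df$delta else NA_real_,
               stringsAsFactors = FALSE),
    include_self_pairs = TRUE, origin = "external")
  df$pred_delta <- predict_delta(model, pairs)
  utils::write.csv(df, out, row.names = FALSE)
  write_manifest(run_manifest("predict", config = fl,
                              inputs = pairs_csv),
                 paste0(out, ".manifest.json"))
  cli_log("wrote predictions for ", nrow(df), " pairs to ", out)
  0L
}

cli_invariants <- function(fl) {
  bundle <- flag_chr(fl, "model") %||% stop("--model is required")
  input <- flag_chr(fl, "in") %||% stop("--in is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  if (!dir.exists(bundle)) stop("model bundle not found: ", bundle)
  model <- load_model(bundle)
  ds <- mol_dataset_from_csv(input)
  rep <- invariant_report(model, ds,
                          max_triplets = flag_num(fl, "max-triplets", 1e5),
                          seed = flag_num(fl, "seed", 1))
  invariant_report_to_json(rep, out)
  write_manifest(run_manifest("invariants", config = fl, inputs = input),
                 paste0(out, ".manifest.json"))
  cli_log("invariant report at ", out)
  0L
}

cli_report <- function(fl) {
  pred_csv <- flag_chr(fl, "pred") %||% stop("--pred is required")
  out <- flag_chr(fl, "out") %||% stop("--out is required")
  df <- utils::read.csv(pred_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("delta", "pred_delta") %in% names(df)))
  m <- suppressWarnings(compute_metrics(df$delta, df$pred_delta))
  mag <- if (nrow(df) >= 10)
    suppressWarnings(magnitude_analysis(df$delta, df$pred_delta)) else NULL
  jsonlite::write_json(list(metrics = unclass(m), magnitude = mag),
                       out, auto_unbox = TRUE, digits = NA)
  write_manifest(run_manifest("report", config = fl, inputs = pred_csv),
                 paste0(out, ".manifest.json"))
  cli_log("report at ", out)
  0L
}
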