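# Synthetic molecule libraries with a controllable additive ground truth.
# Molecules are built by decorating ring cores with substituents; the
# noiseless property is scaffold base + sum of fragment contributions, which
# makes pairwise differences exactly known and lets every other module be
# exercised without external downloads. Values live on a log-like scale
# (range roughly -1..5, SD near 1), matching how ADMET endpoints are
# modelled after log transformation.

# ring cores as templates; {k} marks substitution sites. Base values (like
# the fragment contributions below) are multiples of 1/32: such dyadic
# numbers are exact in binary floating point, so latent sums, pair
# differences and triplet telescoping are all bit-exact.
default_scaffold_library <- function() {
  list(
    benzene     = list(template = "c1cc({1})cc({2})c1{3}",      base = 2.0),
    pyridine    = list(template = "c1cc({1})cnc1{2}",           base = 1.4375),
    cyclohexane = list(template = "C1CC({1})CC({2})C1{3}",      base = 2.6875),
    furan       = list(template = "c1cc({1})oc1{2}",            base = 1.15625),
    thiophene   = list(template = "c1cc({1})sc1{2}",            base = 1.75),
    naphthalene = list(template = "c1ccc2cc({1})c({2})cc2c1{3}", base = 3.09375)
  )
}

# fragment -> additive contribution to the latent property (dyadic grid)
default_contribution_map <- function() {
  c("F" = 0.25, "Cl" = 0.6875, "Br" = 0.9375,
    "C" = 0.3125, "CC" = 0.5625, "CCC" = 0.84375, "C(C)C" = 0.75,
    "O" = -0.59375, "OC" = -0.1875, "N" = -0.4375,
    "C#N" = -0.71875, "C(=O)O" = -1.0625)
}

#' Configuration for the synthetic library generator
#'
#' @param n_molecules number of distinct molecules to emit (the real
#'   benchmark tables this emulates run from ~250 to ~1350 molecules).
#' @param scaffold_library named list of cores, each
#'   `list(template = <SMILES with {k} sites>, base = <real>)`.
#' @param substituent_library character vector of substituent SMILES
#'   fragments; must be a subset of `names(contribution_map)`.
#' @param contribution_map named numeric vector: fragment -> additive
#'   contribution to the latent value.
#' @param noise_sd standard deviation of Gaussian observation noise added on
#'   the (log-scale) value; default 0.1.
#' @param assay_offset constant added to every observed value (emulates a
#'   systematic assay shift; pairing cancels it exactly).
#' @param seed generator seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_molecules = 600,
                             scaffold_library = default_scaffold_library(),
                             substituent_library = names(default_contribution_map()),
                             contribution_map = default_contribution_map(),
                             noise_sd = 0.1,
                             assay_offset = 0,
                             seed = 1) {
  stopifnot(n_molecules >= 2, noise_sd >= 0,
            length(scaffold_library) >= 1, length(substituent_library) >= 1,
            all(substituent_library %in% names(contribution_map)))
  structure(list(n_molecules = n_molecules, scaffold_library = scaffold_library,
                 substituent_library = substituent_library,
                 contribution_map = contribution_map, noise_sd = noise_sd,
                 assay_offset = assay_offset, seed = seed),
            class = "generator_config")
}

n_sites <- function(template) {
  length(gregexpr("\\{[0-9]+\\}", template)[[1]][
    gregexpr("\\{[0-9]+\\}", template)[[1]] > 0])
}

fill_template <- function(template, subs) {
  out <- template
  for (k in seq_along(subs)) {
    tag <- sprintf("{%d}", k)
    if (subs[k] == "") {
      out <- gsub(paste0("(", tag, ")"), "", out, fixed = TRUE)
      out <- gsub(tag, "", out, fixed = TRUE)
    } else {
      out <- gsub(tag, subs[k], out, fixed = TRUE)
    }
  }
  out
}

#' Generate a synthetic property dataset
#'
#' Samples distinct decorated scaffolds until `n_molecules` unique canonical
#' structures are found. The latent (noiseless) value of a molecule is its
#' scaffold base plus the sum of its fragment contributions; the observed
#' value adds `rnorm(noise_sd)` and the constant `assay_offset`. For two
#' molecules on the same scaffold the true difference is therefore exactly
#' the difference of their substituent contributions at zero noise.
#'
#' @param config a [generator_config()].
#' @return a `mol_dataset` with extra columns `noiseless` (latent value) and
#'   `core` (scaffold name); observed value in `value`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lib <- config$scaffold_library
  subs <- config$substituent_library
  contrib <- config$contribution_map
  site_counts <- vapply(lib, function(s) n_sites(s$template), integer(1))
  capacity <- sum((length(subs) + 1)^site_counts)
  if (config$n_molecules > 0.8 * capacity)
    stop(sprintf(paste0("requested %d molecules but the fragment grammar ",
                        "supports only ~%d distinct structures"),
                 config$n_molecules, capacity))
  with_seed(derive_seed(config$seed, 1), {
    seen <- character(0)
    rows <- list()
    attempts <- 0
    while (length(rows) < config$n_molecules) {
      attempts <- attempts + 1
      if (attempts > 60 * config$n_molecules)
        stop("could not realize enough distinct structures")
      core_i <- sample.int(length(lib), 1)
      core <- lib[[core_i]]
      chosen <- sample(c("", subs), site_counts[core_i], replace = TRUE)
      smi <- fill_template(core$template, chosen)
      can <- canonicalize_smiles(smi, strict = FALSE)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      rows[[length(rows) + 1]] <- list(
        smiles = can,
        core = names(lib)[core_i],
        noiseless = core$base + sum(contrib[chosen[chosen != ""]]))
    }
    noiseless <- vapply(rows, `[[`, numeric(1), "noiseless")
    # noise is quantized to the 2^-20 grid: observations then stay dyadic,
    # so an exactly representable assay offset (integers, halves, ...)
    # cancels bit-exactly in every pairwise difference
    noise <- round(stats::rnorm(length(rows), sd = config$noise_sd) * 2^20) / 2^20
    observed <- noiseless + noise + config$assay_offset
    df <- data.frame(
      mol_id = sprintf("s%05d", seq_along(rows)),
      smiles = vapply(rows, `[[`, character(1), "smiles"),
      value = observed, stringsAsFactors = FALSE)
    ds <- new_mol_dataset(df, name = sprintf("synthetic_n%d", config$n_molecules),
                          transform = transform_spec("identity"),
                          provenance = list())
    ds$noiseless <- noiseless
    ds$core <- vapply(rows, `[[`, character(1), "core")
    attr(ds, "generator_config") <- config
    ds
  })
}

#' Generate a suite of synthetic benchmark datasets
#'
#' One dataset per (size, noise level) combination, each with a sub-seed
#' derived from the master seed. Used to study how diagnostics and
#' cross-validated error co-vary with data quality.
#'
#' @param sizes integer vector of dataset sizes.
#' @param noise_levels numeric vector of observation-noise SDs.
#' @param seed master seed.
#' @param assay_offset passed through to each dataset.
#' @return named list of `mol_dataset` objects
#'   (`n<size>_noise<level>`).
#' @export
make_benchmark_suite <- function(sizes, noise_levels, seed = 1, assay_offset = 0) {
  stopifnot(length(sizes) >= 1, length(noise_levels) >= 1)
  combos <- expand.grid(size = sizes, noise = noise_levels)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- generator_config(n_molecules = combos$size[i],
                            noise_sd = combos$noise[i],
                            assay_offset = assay_offset,
                            seed = derive_seed(seed, 100 + i))
    ds <- generate_library(cfg)
    attr(ds, "name") <- sprintf("n%d_noise%g", combos$size[i], combos$noise[i])
    ds
  })
  names(out) <- sprintf("n%d_noise%g", combos$size, combos$noise)
  out
}
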