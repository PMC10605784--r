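# Dataset curation: reading molecule/property tables, filtering qualifier and
# invalid rows, canonical deduplication, and value transforms. Every removal
# is counted per rule in a provenance log so curation is auditable and
# byte-reproducible.

#' Create a value-transform specification
#'
#' Properties spanning orders of magnitude (clearances, solubilities,
#' permeabilities) are modelled on the log10 scale; `pre_offset` is added
#' before the log for assays whose raw values can be zero (e.g. renal
#' clearance incremented by one). Properties that can be negative (free
#' energies) use the identity transform.
#'
#' @param kind "log10" or "identity".
#' @param pre_offset non-negative constant added before the log;
#'   must be 0 for the identity transform.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("log10", "identity"), pre_offset = 0) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(pre_offset, "pre_offset")
  if (pre_offset < 0) stop("`pre_offset` must be >= 0")
  if (kind == "identity" && pre_offset != 0)
    stop("identity transform does not admit a pre-offset")
  structure(list(kind = kind, pre_offset = pre_offset), class = "transform_spec")
}

#' Apply a value transform
#'
#' @param values numeric vector of raw property values.
#' @param spec a [transform_spec()].
#' @return transformed numeric vector.
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"), is.numeric(values))
  if (spec$kind == "identity") return(values)
  shifted <- values + spec$pre_offset
  bad <- which(!is.finite(shifted) | shifted <= 0)
  if (length(bad))
    stop("log10 transform undefined (value + pre_offset <= 0) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  log10(shifted)
}

#' Read a molecule/property table from CSV
#'
#' @param path CSV file with a header.
#' @param smiles_col,value_col column names holding the SMILES and the
#'   property value (value may carry a leading ">" or "<" qualifier).
#' @return a data.frame of raw records: `smiles_text`, `value_text`,
#'   `source_row`.
#' @export
read_property_table <- function(path, smiles_col = "smiles", value_col = "value") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_col %in% names(df))
    stop("column '", smiles_col, "' not found in ", path)
  if (!value_col %in% names(df))
    stop("column '", value_col, "' not found in ", path)
  data.frame(smiles_text = as.character(df[[smiles_col]]),
             value_text = trimws(as.character(df[[value_col]])),
             source_row = seq_len(nrow(df)),
             stringsAsFactors = FALSE)
}

# locale-independent numeric parsing (decimal + scientific notation)
parse_value_text <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Filter raw records by the standard curation rules
#'
#' Removes rows whose value carries a ">" or "<" qualifier (censored
#' measurements cannot anchor a regression target), rows whose value does not
#' parse as a number, and rows whose SMILES fails molecular parsing. Removal
#' counts per rule are recorded in the `provenance` attribute.
#'
#' @param raw data.frame from [read_property_table()].
#' @return the surviving rows, with a `provenance` attribute (named list of
#'   counts by rule).
#' @export
parse_table <- function(raw) {
  stopifnot(nrow(raw) >= 1, all(c("smiles_text", "value_text") %in% names(raw)))
  prov <- list()
  qual <- grepl("^[<>]", raw$value_text)
  prov$qualifier <- sum(qual)
  raw <- raw[!qual, , drop = FALSE]
  num <- parse_value_text(raw$value_text)
  bad_val <- is.na(num)
  prov$invalid_value <- sum(bad_val)
  raw <- raw[!bad_val, , drop = FALSE]
  ok <- valid_smiles(raw$smiles_text)
  prov$invalid_smiles <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) == 0)
    stop("no usable rows remain after filtering", call. = FALSE)
  attr(raw, "provenance") <- prov
  raw
}

#' Curate a raw table into a property dataset
#'
#' Full curation: optional user-supplied SMILES substitutions (for known
#' notation errors in a source; corrections are never guessed automatically),
#' qualifier/validity filtering, canonicalization, within-dataset
#' deduplication on canonical structure (first occurrence kept), and the
#' value transform.
#'
#' @param raw data.frame of raw records (see [read_property_table()]).
#' @param name dataset name.
#' @param transform a [transform_spec()].
#' @param substitutions optional data.frame with columns `from`, `to`:
#'   verbatim SMILES replacements applied before any filtering.
#' @return a `mol_dataset`: data.frame with `mol_id`, `smiles` (canonical),
#'   `value`; attributes `name`, `transform`, `provenance`.
#' @export
curate_dataset <- function(raw, name = "dataset",
                           transform = transform_spec("identity"),
                           substitutions = NULL) {
  if (!is.null(substitutions)) {
    stopifnot(all(c("from", "to") %in% names(substitutions)))
    idx <- match(raw$smiles_text, substitutions$from)
    hit <- !is.na(idx)
    raw$smiles_text[hit] <- substitutions$to[idx[hit]]
  }
  kept <- parse_table(raw)
  prov <- attr(kept, "provenance")
  if (!is.null(substitutions)) prov$substituted <- sum(!is.na(idx) & hit)
  can <- canonicalize_smiles(kept$smiles_text)
  dup <- duplicated(can)
  prov$duplicate_structure <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]
  can <- can[!dup]
  values <- apply_transform(parse_value_text(kept$value_text), transform)
  if (length(values) < 2)
    stop("curated dataset must contain at least 2 molecules", call. = FALSE)
  new_mol_dataset(
    data.frame(mol_id = sprintf("m%05d", kept$source_row),
               smiles = can, value = values, stringsAsFactors = FALSE),
    name = name, transform = transform, provenance = prov)
}

new_mol_dataset <- function(df, name, transform, provenance = list()) {
  stopifnot(all(c("mol_id", "smiles", "value") %in% names(df)))
  if (anyDuplicated(df$mol_id)) stop("mol_id values must be unique")
  if (anyDuplicated(df$smiles)) stop("canonical SMILES must be unique within a dataset")
  if (!all(is.finite(df$value))) stop("property values must be finite")
  rownames(df) <- NULL
  structure(df, name = name, transform = transform, provenance = provenance,
            class = c("mol_dataset", "data.frame"))
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("<mol_dataset '%s'>: %d molecules, transform = %s\n",
              attr(x, "name"), nrow(x), attr(x, "transform")$kind))
  prov <- attr(x, "provenance")
  if (length(prov))
    cat("  removed:", paste(sprintf("%s=%d", names(prov), unlist(prov)),
                            collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Remove candidate molecules similar to a reference set
#'
#' External-set deduplication: drops candidates whose maximum fingerprint
#' Tanimoto similarity to any reference molecule reaches `threshold`
#' (threshold 1.0 removes structurally identical molecules only).
#'
#' @param candidates,reference `mol_dataset` objects.
#' @param threshold similarity cutoff in `[0, 1]`.
#' @param radius,n_bits fingerprint parameters (see [morgan_fingerprints()]).
#' @return the filtered candidate dataset with the removal count appended to
#'   its provenance log.
#' @export
dedup_against <- function(candidates, reference, threshold = 1.0,
                          radius = 2, n_bits = 2048) {
  stopifnot(inherits(candidates, "mol_dataset"), inherits(reference, "mol_dataset"),
            threshold >= 0, threshold <= 1)
  if (nrow(reference) == 0 || nrow(candidates) == 0) return(candidates)
  fp_c <- morgan_fingerprints(candidates$smiles, radius, n_bits)
  fp_r <- morgan_fingerprints(reference$smiles, radius, n_bits)
  sim <- tanimoto_cross(fp_c, fp_r)
  drop <- apply(sim, 1, max) >= threshold
  prov <- attr(candidates, "provenance")
  prov$dedup_against_reference <- sum(drop)
  out <- candidates[!drop, , drop = FALSE]
  new_mol_dataset(as.data.frame(out), name = attr(candidates, "name"),
                  transform = attr(candidates, "transform"), provenance = prov)
}

#' Write a curated dataset and its provenance log
#'
#' @param dataset a `mol_dataset`.
#' @param path output CSV path; the provenance JSON is written next to it
#'   (or at `provenance_path` if given).
#' @param provenance_path optional explicit JSON path.
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, path, provenance_path = NULL) {
  stopifnot(inherits(dataset, "mol_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  pp <- provenance_path %||% sub("\\.csv$", "", path)
  if (identical(pp, path) || !grepl("\\.json$", pp)) pp <- paste0(pp, ".provenance.json")
  jsonlite::write_json(
    list(name = attr(dataset, "name"),
         n_molecules = nrow(dataset),
         transform = unclass(attr(dataset, "transform")),
         removed = attr(dataset, "provenance")),
    pp, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, provenance = pp))
}
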