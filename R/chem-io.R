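# OpenBabel-backed SMILES handling. All chemistry (parsing, canonical SMILES
# emission, fingerprint hashing) is delegated to OpenBabel via ChemmineOB and
# the obabel CLI; this file only routes strings in and out.

# OpenBabel is permissive and will quietly "repair" some malformed SMILES
# (e.g. an unbalanced parenthesis), so validity = syntactic pre-check AND a
# successful OpenBabel parse.
smiles_syntax_ok <- function(smiles) {
  allowed <- c(LETTERS, letters, 0:9,
               "@", "+", "-", "[", "]", "(", ")", "=", "#", "$",
               ":", "/", "\\", "%", ".", "*")
  check_one <- function(s) {
    if (is.na(s) || !nzchar(s) || grepl("[[:space:]]", s)) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% allowed)) return(FALSE)
    for (pair in list(c("(", ")"), c("[", "]"))) {
      depth <- cumsum((ch == pair[1]) - (ch == pair[2]))
      if (any(depth < 0) || depth[length(depth)] != 0) return(FALSE)
    }
    TRUE
  }
  vapply(smiles, check_one, logical(1), USE.NAMES = FALSE)
}

# one batched OpenBabel conversion keyed by synthetic titles; entries the
# parser rejects simply drop out of the output and come back as NA
ob_convert_by_title <- function(smiles, out_format) {
  n <- length(smiles)
  ids <- paste0("x", seq_len(n))
  input <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", out_format, input),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  if (!nzchar(out)) return(res)
  if (out_format == "CAN") {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        idx <- match(trimws(p[2]), ids)
        if (!is.na(idx)) res[idx] <- p[1]
      }
    }
  } else {
    stop("unsupported output format: ", out_format)
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form so that any two notations of
#' the same molecule map to one string. Idempotent: canonical input is
#' returned unchanged.
#'
#' @param smiles character vector of SMILES.
#' @param strict if `TRUE` (default) an unparseable SMILES raises an error
#'   naming the offending string; if `FALSE` it yields `NA` in the output.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  res <- rep(NA_character_, length(smiles))
  ok <- smiles_syntax_ok(smiles)
  if (any(ok)) res[ok] <- ob_convert_by_title(smiles[ok], "CAN")
  if (strict && anyNA(res)) {
    bad <- unique(smiles[is.na(res)])
    stop("invalid SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
         call. = FALSE)
  }
  res
}

#' Test whether SMILES strings are valid
#'
#' @param smiles character vector.
#' @return logical vector; `TRUE` where the string parses as a molecule.
#' @export
valid_smiles <- function(smiles) {
  !is.na(canonicalize_smiles(smiles, strict = FALSE))
}

# SMILES -> V2000 MOL blocks (one string per molecule, NA where unparseable)
smiles_to_molblocks <- function(smiles) {
  n <- length(smiles)
  ids <- paste0("x", seq_len(n))
  input <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- ChemmineOB::convertFormat("SMI", "SDF", input)
  blocks <- strsplit(out, "\\${4}\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  res <- rep(NA_character_, n)
  for (b in blocks) {
    title <- trimws(strsplit(b, "\n", fixed = TRUE)[[1]][1])
    idx <- match(title, ids)
    if (!is.na(idx)) res[idx] <- sub("^\n+", "", b)
  }
  res
}
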