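# Circular (Morgan/ECFP-style) substructure fingerprints, pair concatenation
# and Tanimoto similarity. Hashing is OpenBabel's extended-connectivity
# implementation; batches run through one obabel process per call, and the
# parsed bit count is checked against the count obabel prints for each record.

ecfp_name <- function(radius) {
  stopifnot(radius %in% 0:5)
  paste0("ECFP", 2L * radius)
}

#' Morgan circular fingerprints for a set of molecules
#'
#' Fixed-length binary substructure fingerprints hashing circular atom
#' neighbourhoods up to `radius` bonds (the field's default for property
#' models: radius 2, 2048 bits). Deterministic in the canonical structure:
#' any two notations of the same molecule give identical bits.
#'
#' @param smiles character vector of valid SMILES (duplicates allowed).
#' @param radius neighbourhood radius in bonds (default 2, i.e. ECFP4).
#' @param n_bits fingerprint length (default 2048).
#' @return a sparse 0/1 `Matrix::dgCMatrix` with one row per input SMILES
#'   (in input order) and `n_bits` columns.
#' @export
morgan_fingerprints <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            n_bits >= 32, n_bits %% 32 == 0)
  can <- canonicalize_smiles(smiles)
  uniq <- unique(can)
  fp <- obabel_fingerprints(uniq, ecfp_name(radius), n_bits)
  out <- fp[match(can, uniq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Morgan fingerprint of a single molecule
#'
#' @inheritParams morgan_fingerprints
#' @return integer 0/1 vector of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(length(smiles) == 1)
  as.integer(morgan_fingerprints(smiles, radius, n_bits)[1, ])
}

obabel_fingerprints <- function(smiles, fp_name, n_bits) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) stop("obabel executable not found on PATH")
  ids <- paste0("x", seq_along(smiles))
  smi_file <- tempfile(fileext = ".smi")
  fpt_file <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(smi_file, fpt_file)), add = TRUE)
  writeLines(paste(smiles, ids), smi_file)
  status <- system2(obabel,
                    c(smi_file, "-ofpt", paste0("-xf", fp_name),
                      "-xN", n_bits, "-xh", "-O", fpt_file),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fpt_file)) stop("obabel fingerprinting failed")
  lines <- readLines(fpt_file)
  starts <- grep("^>", lines)
  if (length(starts) != length(smiles))
    stop("fingerprint output incomplete (", length(starts), " of ",
         length(smiles), " molecules)")
  rows <- integer(0); cols <- integer(0)
  order_idx <- integer(length(smiles))
  ends <- c(starts[-1] - 1L, length(lines))
  for (k in seq_along(starts)) {
    header <- lines[starts[k]]
    id <- sub("^>\\s*(\\S+).*$", "\\1", header)
    i <- match(id, ids)
    if (is.na(i)) stop("unexpected fingerprint record: ", header)
    order_idx[k] <- i
    hex_words <- unlist(strsplit(trimws(lines[(starts[k] + 1L):ends[k]]),
                                 "[[:space:]]+"))
    hex_words <- hex_words[nzchar(hex_words)]
    if (length(hex_words) != n_bits / 32)
      stop("expected ", n_bits / 32, " words, got ", length(hex_words))
    bits <- parse_hex_words(hex_words)
    claimed <- suppressWarnings(as.integer(sub("^>\\s*\\S+\\s+(\\d+) bits set.*$",
                                               "\\1", header)))
    if (!is.na(claimed) && claimed != length(bits))
      stop("fingerprint parse mismatch for ", id, ": ", length(bits),
           " vs claimed ", claimed)
    rows <- c(rows, rep.int(i, length(bits)))
    cols <- c(cols, bits)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(length(smiles), n_bits))
}

# 8-hex-digit words -> 1-based global bit positions; within a word the lower
# hex digits hold bits 0-15 (mapping is fixed and bijective per word, which
# is all Tanimoto/identity comparisons require)
parse_hex_words <- function(hex_words) {
  nwords <- length(hex_words)
  hi <- strtoi(substr(hex_words, 1, 4), 16L)
  lo <- strtoi(substr(hex_words, 5, 8), 16L)
  bits <- integer(0)
  for (w in seq_len(nwords)) {
    b_lo <- which(as.logical(intToBits(lo[w])[1:16])) - 1L
    b_hi <- which(as.logical(intToBits(hi[w])[1:16])) + 15L
    local <- c(b_lo, b_hi)
    if (length(local)) bits <- c(bits, (w - 1L) * 32L + local + 1L)
  }
  bits
}

#' Concatenate two fingerprints into a paired feature vector
#'
#' Ordered concatenation (first molecule's bits, then the second's); swapping
#' the arguments swaps the halves, so direction information is preserved.
#'
#' @param a,b equal-length 0/1 fingerprint vectors.
#' @return integer 0/1 vector of length `2 * length(a)`.
#' @export
concat_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("fingerprint lengths differ: ", length(a), " vs ", length(b))
  c(a, b)
}

# rows of fp indexed by pair ends -> sparse pair-feature matrix (n x 2L)
pair_feature_matrix <- function(fp, first_idx, second_idx) {
  cbind(fp[first_idx, , drop = FALSE], fp[second_idx, , drop = FALSE])
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits. The degenerate case of two
#' all-zero fingerprints (both featureless) is defined as 1 with a warning.
#'
#' @param a,b equal-length 0/1 fingerprint vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints are all-zero; defining similarity as 1")
    return(1)
  }
  sum(a & b) / un
}

# all-pairs Tanimoto between two fingerprint matrices (rows = molecules)
tanimoto_cross <- function(fp_a, fp_b) {
  inter <- as.matrix(fp_a %*% Matrix::t(fp_b))
  ca <- Matrix::rowSums(fp_a)
  cb <- Matrix::rowSums(fp_b)
  un <- outer(ca, cb, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  sim
}
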