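# Minimal V2000 MOL handling plus molecular-graph construction for the
# message-passing encoder and for Bemis-Murcko scaffold extraction.
#
# A dedicated reader/writer is used (rather than an SDF container package)
# because graph building needs exact atom/bond indices, single-heavy-atom
# molecules must round-trip, and scaffold extraction edits blocks in place.
# Chemistry interpretation still belongs to OpenBabel: blocks are produced by
# it and edited blocks are handed back to it for canonical SMILES emission.

parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  elements <- character(natoms)
  for (i in seq_len(natoms)) {
    elements[i] <- trimws(substr(lines[4 + i], 32, 34))
  }
  bonds <- if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    data.frame(
      from  = as.integer(substr(bl, 1, 3)),
      to    = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  charges <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charges[f[2 * j]] <- f[2 * j + 1]
  }
  list(elements = elements, charges = charges, bonds = bonds)
}

write_molblock <- function(elements, bonds, charges = NULL) {
  natoms <- length(elements)
  nbonds <- nrow(bonds)
  header <- c("", "  deltamol", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, elements)
  bond_lines <- if (nbonds > 0)
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order) else character(0)
  chg_lines <- character(0)
  if (!is.null(charges) && any(charges != 0)) {
    idx <- which(charges != 0)
    chg_lines <- sprintf("M  CHG%3d%s", length(idx),
                         paste(sprintf("%4d%4d", idx, charges[idx]), collapse = ""))
  }
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END"), collapse = "\n")
}

# edited MOL blocks -> canonical SMILES, batched through one OpenBabel call
molblocks_to_cansmi <- function(blocks) {
  n <- length(blocks)
  ids <- paste0("x", seq_len(n))
  tagged <- vapply(seq_len(n), function(i) {
    sub("^[^\n]*", ids[i], blocks[i])  # first line of a MOL block is the title
  }, character(1))
  input <- paste0(paste0(tagged, "\n$$$$\n"), collapse = "")
  out <- ChemmineOB::convertFormat("SDF", "CAN", input)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, n)
  for (ln in lines) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) >= 2) {
      idx <- match(trimws(p[2]), ids)
      if (!is.na(idx)) res[idx] <- p[1]
    }
  }
  res
}

# bonds that sit on a cycle (non-bridges), via DFS bridge finding; graphs are
# molecule-sized so an O(V+E) R implementation is ample
ring_bonds <- function(natoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(logical(0))
  adj <- vector("list", natoms)
  for (i in seq_len(nb)) {
    adj[[bonds$from[i]]] <- c(adj[[bonds$from[i]]], i)
    adj[[bonds$to[i]]] <- c(adj[[bonds$to[i]]], i)
  }
  disc <- low <- integer(natoms)
  visited <- logical(natoms)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(natoms)) {
    if (visited[root]) next
    # iterative DFS: stack of (node, parent-edge, next-neighbor-pointer)
    stack <- list(list(v = root, pe = 0L, ptr = 1L))
    visited[root] <- TRUE
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      edges <- adj[[v]]
      if (top$ptr <= length(edges)) {
        stack[[length(stack)]]$ptr <- top$ptr + 1L
        e <- edges[top$ptr]
        if (e == top$pe) next
        u <- if (bonds$from[e] == v) bonds$to[e] else bonds$from[e]
        if (!visited[u]) {
          visited[u] <- TRUE
          timer <- timer + 1L
          disc[u] <- low[u] <- timer
          stack[[length(stack) + 1L]] <- list(v = u, pe = e, ptr = 1L)
        } else {
          low[v] <- min(low[v], disc[u])
          stack[[length(stack)]]$low_touch <- TRUE
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[top$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# element vocabulary for atom one-hots; anything else maps to "other"
MPNN_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

atom_feature_dim <- function() length(MPNN_ELEMENTS) + 1 + 6 + 1
bond_feature_dim <- function() 5

#' Build a molecular graph from a SMILES string
#'
#' Converts a molecule into the atom/bond representation consumed by the
#' message-passing encoder: per-atom feature vectors (element one-hot, degree
#' one-hot, ring membership) and directed bonds (each undirected bond yields
#' two directed bonds) with bond-order and ring features.
#'
#' @param smiles character vector of valid SMILES.
#' @return a list of graphs; each has `elements`, `atom_features`
#'   (atoms x features), `bonds` (directed: `src`, `dst`, `rev` index) and
#'   `bond_features`.
#' @export
molecular_graphs <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  blocks <- smiles_to_molblocks(can)
  lapply(seq_along(blocks), function(i) {
    if (is.na(blocks[i])) stop("could not build MOL block for: ", smiles[i])
    mol_to_graph(parse_molblock(blocks[[i]]))
  })
}

mol_to_graph <- function(mol) {
  natoms <- length(mol$elements)
  nb <- nrow(mol$bonds)
  degree <- integer(natoms)
  if (nb > 0) {
    tb <- table(factor(c(mol$bonds$from, mol$bonds$to), levels = seq_len(natoms)))
    degree <- as.integer(tb)
  }
  rb <- ring_bonds(natoms, mol$bonds)
  ring_atom <- logical(natoms)
  if (nb > 0) {
    ring_atom[unique(c(mol$bonds$from[rb], mol$bonds$to[rb]))] <- TRUE
  }
  elem_idx <- match(mol$elements, MPNN_ELEMENTS)
  elem_idx[is.na(elem_idx)] <- length(MPNN_ELEMENTS) + 1L
  Fa <- atom_feature_dim()
  X <- matrix(0, natoms, Fa)
  X[cbind(seq_len(natoms), elem_idx)] <- 1
  deg_idx <- pmin(degree, 5L) + 1L  # one-hot over degree 0..5+
  X[cbind(seq_len(natoms), length(MPNN_ELEMENTS) + 1 + deg_idx)] <- 1
  X[, Fa] <- as.numeric(ring_atom)
  if (nb > 0) {
    src <- c(mol$bonds$from, mol$bonds$to)
    dst <- c(mol$bonds$to, mol$bonds$from)
    rev <- c(nb + seq_len(nb), seq_len(nb))
    ord <- pmin(mol$bonds$order, 4L)
    E <- matrix(0, 2 * nb, bond_feature_dim())
    E[cbind(seq_len(2 * nb), rep(ord, 2))] <- 1
    E[, 5] <- rep(as.numeric(rb), 2)
    bonds <- data.frame(src = src, dst = dst, rev = rev)
  } else {
    E <- matrix(0, 0, bond_feature_dim())
    bonds <- data.frame(src = integer(0), dst = integer(0), rev = integer(0))
  }
  list(elements = mol$elements, atom_features = X, bonds = bonds,
       bond_features = E, degree = degree, ring_atom = ring_atom)
}

#' Bemis-Murcko scaffold of molecules
#'
#' Ring systems plus the linkers connecting them, with side chains removed.
#' Computation: iteratively delete terminal (degree-1) atoms until only rings
#' and linkers remain, then restore atoms attached to that core by a double or
#' triple bond (so e.g. a linker carbonyl keeps its oxygen). The scaffold is
#' returned as a canonical SMILES; a fully acyclic molecule has the empty
#' string as its scaffold. Formal charges on pruned neighbours are dropped,
#' which keeps scaffold strings comparable but may differ from conventions
#' that re-balance charge.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of scaffold SMILES ("" for acyclic molecules).
#' @export
murcko_scaffold <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  uniq <- unique(can)
  blocks <- smiles_to_molblocks(uniq)
  out <- character(length(uniq))
  pending_blocks <- character(0)
  pending_idx <- integer(0)
  for (i in seq_along(uniq)) {
    mol <- parse_molblock(blocks[[i]])
    keep <- scaffold_atoms(mol)
    if (length(keep) == 0) { out[i] <- ""; next }
    remap <- match(seq_along(mol$elements), keep)
    b <- mol$bonds[mol$bonds$from %in% keep & mol$bonds$to %in% keep, , drop = FALSE]
    b$from <- remap[b$from]; b$to <- remap[b$to]
    pending_blocks <- c(pending_blocks,
                        write_molblock(mol$elements[keep], b, mol$charges[keep]))
    pending_idx <- c(pending_idx, i)
  }
  if (length(pending_idx)) {
    smi <- molblocks_to_cansmi(pending_blocks)
    if (anyNA(smi)) stop("scaffold SMILES emission failed")
    out[pending_idx] <- smi
  }
  out[match(can, uniq)]
}

# atom indices forming the Murcko framework (rings + linkers + multiply
# bonded attachments); empty integer vector for acyclic molecules
scaffold_atoms <- function(mol) {
  natoms <- length(mol$elements)
  if (nrow(mol$bonds) == 0) return(integer(0))
  alive <- rep(TRUE, natoms)
  repeat {
    deg <- integer(natoms)
    act <- mol$bonds[alive[mol$bonds$from] & alive[mol$bonds$to], , drop = FALSE]
    if (nrow(act) == 0) { alive[] <- FALSE; break }
    tb <- table(factor(c(act$from, act$to), levels = seq_len(natoms)))
    deg <- as.integer(tb)
    drop <- alive & deg <= 1
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  core <- which(alive)
  if (length(core) == 0) return(integer(0))
  # restore double/triple-bonded direct attachments to the core
  att <- with(mol$bonds, (from %in% core & !(to %in% core) & order >= 2) |
                         (to %in% core & !(from %in% core) & order >= 2))
  extra <- unique(c(mol$bonds$from[att], mol$bonds$to[att]))
  sort(unique(c(core, extra)))
}
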