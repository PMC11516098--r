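# Molecule parsing and the 2D chemical graph.
#
# A `csmol_molecule` is a heavy-atom graph parsed from an OpenBabel V2000
# MOL block, with per-atom ring/aromaticity/hybridization perception done
# in-package (only match *counts* are available through ChemmineOB, not
# atom indices). Hydrogens are implicit throughout.

ATOM_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se", "other")

parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  # counts line is the 4th line of a V2000 connection table
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) stop("malformed MOL block", call. = FALSE)
  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(
    as.numeric(substr(atom_lines, 1, 10)),
    as.numeric(substr(atom_lines, 11, 20)),
    as.numeric(substr(atom_lines, 21, 30))
  )
  charge <- integer(n_atoms)
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    b1 <- as.integer(substr(bond_lines, 1, 3))
    b2 <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
  } else {
    b1 <- b2 <- bo <- integer(0)
  }
  # M  CHG property lines override the (deprecated) atom-block charge column
  for (ln in lines[grepl("^M  CHG", lines)]) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) charge[f[2 * i]] <- f[2 * i + 1]
  }
  list(n_atoms = n_atoms, element = elem, xyz = xyz, charge = charge,
       bond_a = b1, bond_b = b2, bond_order = bo)
}

# A bond is in a ring iff removing it leaves its endpoints connected.
perceive_ring_bonds <- function(n_atoms, bond_a, bond_b) {
  m <- length(bond_a)
  in_ring <- logical(m)
  if (m == 0) return(in_ring)
  adj <- vector("list", n_atoms)
  for (k in seq_len(m)) {
    adj[[bond_a[k]]] <- c(adj[[bond_a[k]]], k)
    adj[[bond_b[k]]] <- c(adj[[bond_b[k]]], k)
  }
  for (k in seq_len(m)) {
    # BFS from bond_a[k] to bond_b[k] avoiding bond k
    src <- bond_a[k]; dst <- bond_b[k]
    seen <- logical(n_atoms); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bond_a[e] == v) bond_b[e] else bond_a[e]
        if (w == dst) { found <- TRUE; break }
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    in_ring[k] <- found
  }
  in_ring
}

# Smallest rings: for each ring bond, the shortest cycle through it (BFS),
# deduplicated. A lightweight SSSR stand-in sufficient for aromaticity.
smallest_rings <- function(n_atoms, bond_a, bond_b, ring_bond) {
  rings <- list()
  keys <- character(0)
  adj <- vector("list", n_atoms)
  m <- length(bond_a)
  for (k in seq_len(m)) {
    if (!ring_bond[k]) next
    adj[[bond_a[k]]] <- c(adj[[bond_a[k]]], k)
    adj[[bond_b[k]]] <- c(adj[[bond_b[k]]], k)
  }
  for (k in seq_len(m)) {
    if (!ring_bond[k]) next
    src <- bond_a[k]; dst <- bond_b[k]
    # BFS shortest path dst -> src avoiding bond k (ring bonds only)
    prev <- integer(n_atoms); prev[] <- NA_integer_
    seen <- logical(n_atoms); seen[dst] <- TRUE
    queue <- dst
    while (length(queue) > 0 && !seen[src]) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bond_a[e] == v) bond_b[e] else bond_a[e]
        if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w) }
      }
    }
    if (!seen[src]) next
    path <- src
    while (path[length(path)] != dst) path <- c(path, prev[path[length(path)]])
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

# Hückel-style aromaticity on the kekulized graph: a smallest ring is
# aromatic if every member is sp2-capable and the pi-electron count is
# 4n+2. Contributions: atom with a double/aromatic bond -> 1; N/O/S with
# none -> 2 (lone pair); carbonyl-type exocyclic double bond -> 0 (blocks).
perceive_aromatic <- function(pm, ring_bond) {
  n <- pm$n_atoms
  has_double <- logical(n)  # double bond within the ring system
  exo_double <- logical(n)  # double bond pointing out of all rings
  ring_atom <- logical(n)
  ring_atom[c(pm$bond_a[ring_bond], pm$bond_b[ring_bond])] <- TRUE
  for (k in seq_along(pm$bond_a)) {
    if (pm$bond_order[k] == 2 || pm$bond_order[k] == 4) {
      a <- pm$bond_a[k]; b <- pm$bond_b[k]
      if (ring_atom[a] && ring_atom[b]) {
        has_double[a] <- TRUE; has_double[b] <- TRUE
      } else {
        exo_double[a] <- TRUE; exo_double[b] <- TRUE
      }
    }
  }
  rings <- smallest_rings(n, pm$bond_a, pm$bond_b, ring_bond)
  aromatic <- logical(n)
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    pi <- 0L; ok <- TRUE
    for (a in ring) {
      el <- pm$element[a]
      if (has_double[a]) {
        pi <- pi + 1L
      } else if (exo_double[a]) {
        ok <- FALSE; break      # e.g. cyclohexanone carbonyl carbon
      } else if (el %in% c("N", "O", "S") ||
                 (el == "C" && pm$charge[a] != 0)) {
        pi <- pi + 2L           # lone-pair donor
      } else {
        ok <- FALSE; break      # saturated carbon
      }
    }
    if (ok && pi %% 4L == 2L) aromatic[ring] <- TRUE
  }
  aromatic
}

perceive_hybridization <- function(pm) {
  n <- pm$n_atoms
  n_double <- integer(n); n_triple <- integer(n)
  for (k in seq_along(pm$bond_a)) {
    a <- pm$bond_a[k]; b <- pm$bond_b[k]
    if (pm$bond_order[k] == 2) { n_double[a] <- n_double[a] + 1L; n_double[b] <- n_double[b] + 1L }
    if (pm$bond_order[k] == 3) { n_triple[a] <- n_triple[a] + 1L; n_triple[b] <- n_triple[b] + 1L }
  }
  ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(n_double == 1, "sp2", "sp3"))
}

count_rotatable_bonds <- function(pm, ring_bond, degree) {
  # single, non-ring bonds between two non-terminal heavy atoms,
  # amide C-N excluded
  n_rot <- 0L
  # carbons double-bonded to O (carbonyl) for the amide rule
  carbonyl_c <- logical(pm$n_atoms)
  for (k in seq_along(pm$bond_a)) {
    if (pm$bond_order[k] == 2) {
      a <- pm$bond_a[k]; b <- pm$bond_b[k]
      if (pm$element[a] == "C" && pm$element[b] == "O") carbonyl_c[a] <- TRUE
      if (pm$element[b] == "C" && pm$element[a] == "O") carbonyl_c[b] <- TRUE
    }
  }
  for (k in seq_along(pm$bond_a)) {
    if (pm$bond_order[k] != 1 || ring_bond[k]) next
    a <- pm$bond_a[k]; b <- pm$bond_b[k]
    if (degree[a] < 2 || degree[b] < 2) next
    amide <- (carbonyl_c[a] && pm$element[b] == "N") ||
             (carbonyl_c[b] && pm$element[a] == "N")
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

#' Parse a SMILES string into a molecule object
#'
#' Canonicalizes the SMILES with OpenBabel, builds the heavy-atom graph,
#' perceives rings/aromaticity/hybridization, and counts bonds and
#' rotatable bonds (single, non-ring bonds between two non-terminal heavy
#' atoms, amide C-N excluded).
#'
#' @param smiles a syntactically valid, single-fragment SMILES string
#' @param id molecule identifier carried through the pipeline
#' @return an object of class `csmol_molecule` with fields `id`, `smiles`
#'   (canonical), `n_heavy_atoms`, `n_bonds`, `n_rotatable_bonds`,
#'   `scaffold_key`, and the parsed graph (`atoms`, `bonds`)
#' @examples
#' m <- parse_molecule("c1ccccc1O", "phenol")
#' m$n_heavy_atoms
#' @export
parse_molecule <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- ob_canonical(smiles)
  if (is.na(can) || !nzchar(can)) {
    stop("invalid SMILES: '", smiles, "'", call. = FALSE)
  }
  if (grepl(".", can, fixed = TRUE)) {
    stop("multi-fragment SMILES not supported (strip salts upstream): '",
         smiles, "'", call. = FALSE)
  }
  pm <- parse_molblock(ob_smiles_to_molblock(can))
  degree <- tabulate(c(pm$bond_a, pm$bond_b), nbins = pm$n_atoms)
  ring_bond <- perceive_ring_bonds(pm$n_atoms, pm$bond_a, pm$bond_b)
  aromatic <- perceive_aromatic(pm, ring_bond)
  ring_atom <- logical(pm$n_atoms)
  ring_atom[c(pm$bond_a[ring_bond], pm$bond_b[ring_bond])] <- TRUE
  hyb <- perceive_hybridization(pm)
  hyb[aromatic] <- "sp2"
  atoms <- data.frame(
    element = pm$element,
    charge = pm$charge,
    degree = degree,
    in_ring = ring_atom,
    aromatic = aromatic,
    hybridization = hyb,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    a1 = pm$bond_a, a2 = pm$bond_b, order = pm$bond_order,
    in_ring = ring_bond,
    aromatic = aromatic[pm$bond_a] & aromatic[pm$bond_b] & ring_bond,
    stringsAsFactors = FALSE
  )
  mol <- structure(list(
    id = id,
    smiles = can,
    n_heavy_atoms = pm$n_atoms,
    n_bonds = length(pm$bond_a),
    n_rotatable_bonds = count_rotatable_bonds(pm, ring_bond, degree),
    scaffold_key = NA_character_,
    atoms = atoms,
    bonds = bonds
  ), class = "csmol_molecule")
  mol$scaffold_key <- murcko_scaffold(mol)
  mol
}

#' @export
print.csmol_molecule <- function(x, ...) {
  cat("<csmol_molecule> ", x$id, "\n  ", x$smiles, "\n  heavy atoms: ",
      x$n_heavy_atoms, "  bonds: ", x$n_bonds, "  rotatable: ",
      x$n_rotatable_bonds, "\n  scaffold: ",
      if (nzchar(x$scaffold_key)) x$scaffold_key else "(acyclic)", "\n",
      sep = "")
  invisible(x)
}

# Serialize a heavy-atom subgraph back to a V2000 MOL block so that
# OpenBabel can canonicalize it (used by the scaffold extractor and the
# SMILES randomizer).
graph_to_molblock <- function(element, charge, bond_a, bond_b, bond_order,
                              title = "frag") {
  n <- length(element); m <- length(bond_a)
  hdr <- c(title, " csmol", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, element)
  bd <- if (m > 0) sprintf("%3d%3d%3d  0  0  0  0", bond_a, bond_b, bond_order) else character(0)
  chg <- character(0)
  nz <- which(charge != 0)
  if (length(nz) > 0) {
    chg <- sprintf("M  CHG%3d%s", length(nz),
                   paste(sprintf("%4d%4d", nz, charge[nz]), collapse = ""))
  }
  paste(c(hdr, at, bd, chg, "M  END", "$$$$"), collapse = "\n")
}

#' Read a .smi library file
#'
#' One molecule per line: SMILES optionally followed by whitespace and an id.
#'
#' @param path file path
#' @return data.frame with columns `smiles`, `id`
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a .smi library file with canonical SMILES
#'
#' @param mols list of `csmol_molecule` or a data.frame with `smiles`, `id`
#' @param path output path
#' @export
write_smi <- function(mols, path) {
  if (is.data.frame(mols)) {
    lines <- paste(mols$smiles, mols$id)
  } else {
    lines <- vapply(mols, function(m) paste(m$smiles, m$id), character(1))
  }
  writeLines(lines, path)
}

#' Read molecules from a CSV with a named SMILES column
#'
#' @param path CSV path
#' @param smiles_col name of the SMILES column
#' @param id_col optional id column; row numbers used when absent
#' @return data.frame with columns `smiles`, `id` (plus all original columns)
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles", id_col = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("no column '", smiles_col, "' in ", path, call. = FALSE)
  }
  df$smiles <- df[[smiles_col]]
  df$id <- if (!is.null(id_col) && id_col %in% names(df)) as.character(df[[id_col]]) else as.character(seq_len(nrow(df)))
  df
}
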