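# Hashed linear-path fingerprints over the heavy-atom graph.
# Used by the surrogate-label kernel, the screening fixture, and as one of
# the baseline fingerprints. OpenBabel fingerprints (FP2/FP3/FP4/MACCS)
# are available alongside through `fingerprint_baseline()`.

# stable 32-bit-ish polynomial string hash (R has no exported stable hash)
.path_hash <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  (h %% nbits) + 1L
}

#' Hashed path fingerprint of a molecule
#'
#' Enumerates simple linear paths of up to `max_len` bonds (atom elements
#' and bond orders, direction-canonicalized) and hashes them into a fixed
#' bit vector.
#'
#' @param mol a `csmol_molecule`
#' @param nbits fingerprint length (default 512)
#' @param max_len maximum path length in bonds (default 4)
#' @return integer 0/1 vector of length `nbits`
#' @export
path_fingerprint <- function(mol, nbits = 512L, max_len = 4L) {
  stopifnot(inherits(mol, "csmol_molecule"))
  n <- mol$n_heavy_atoms
  el <- mol$atoms$element
  el[mol$atoms$aromatic] <- tolower(el[mol$atoms$aromatic])
  adj <- vector("list", n)
  for (k in seq_len(mol$n_bonds)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    o <- if (mol$bonds$aromatic[k]) "~" else as.character(mol$bonds$order[k])
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  keys <- character(0)
  # DFS over simple paths; canonical form = lexicographic min of the two
  # directions, so each path contributes one key
  walk <- function(path, labels) {
    fwd <- paste(labels, collapse = "")
    rev_ <- paste(rev(labels), collapse = "")
    keys[[length(keys) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if ((length(path) - 1L) >= max_len) return(invisible())
    last <- path[length(path)]
    nb <- adj[[last]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- as.integer(nb[r, 1])
      if (nxt %in% path) next
      walk(c(path, nxt), c(labels, nb[r, 2], el[nxt]))
    }
    invisible()
  }
  for (a in seq_len(n)) walk(a, el[a])
  fp <- integer(nbits)
  for (k in unique(keys)) fp[.path_hash(k, nbits)] <- 1L
  fp
}

#' Tanimoto similarity of two bit vectors
#' @param fa,fb 0/1 integer vectors of equal length
#' @export
tanimoto <- function(fa, fb) {
  i <- sum(fa & fb); u <- sum(fa | fb)
  if (u == 0) return(0)
  i / u
}
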