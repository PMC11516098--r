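# Bemis-Murcko scaffold extraction.

#' Murcko scaffold of a molecule
#'
#' Ring systems plus linkers with side chains removed; atoms double-bonded
#' directly to the framework (e.g. carbonyl oxygens on a ring) are retained.
#' Acyclic molecules yield the empty string.
#'
#' @param mol a `csmol_molecule`
#' @return canonical SMILES of the scaffold, or `""` for acyclic molecules
#' @examples
#' murcko_scaffold(parse_molecule("Cc1ccccc1", "toluene"))  # benzene
#' @export
murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "csmol_molecule"))
  if (!any(mol$bonds$in_ring)) return("")
  n <- mol$n_heavy_atoms
  keep <- rep(TRUE, n)
  ba <- mol$bonds$a1; bb <- mol$bonds$a2
  # phase 1: iteratively strip terminal atoms -> rings + linkers
  repeat {
    deg <- tabulate(c(ba[keep[ba] & keep[bb]], bb[keep[ba] & keep[bb]]), nbins = n)
    drop <- keep & deg <= 1 & !mol$atoms$in_ring
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # phase 2: re-attach atoms double-bonded to the framework
  repeat {
    added <- FALSE
    for (k in seq_along(ba)) {
      if (mol$bonds$order[k] >= 2) {
        if (keep[ba[k]] && !keep[bb[k]]) { keep[bb[k]] <- TRUE; added <- TRUE }
        if (keep[bb[k]] && !keep[ba[k]]) { keep[ba[k]] <- TRUE; added <- TRUE }
      }
    }
    if (!added) break
  }
  idx <- which(keep)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  sel <- keep[ba] & keep[bb]
  mb <- graph_to_molblock(
    mol$atoms$element[idx], mol$atoms$charge[idx],
    remap[ba[sel]], remap[bb[sel]], mol$bonds$order[sel],
    title = "scaffold"
  )
  ob_canonical(ob_molblock_to_smiles(mb))
}
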