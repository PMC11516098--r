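# Graph featurization for the encoder.
#
# Node vector layout (width 27, fixed):
#   [1:13]  atom type one-hot over ATOM_VOCAB (slot 13 = "other")
#   [14:17] hybridization one-hot (sp, sp2, sp3, other)
#   [18:22] formal charge one-hot (-2, -1, 0, +1, +2; clamped)
#   [23:25] chiral tag one-hot (none, CW, CCW)
#   [26]    in-ring flag
#   [27]    aromatic flag
# Edge vector layout (width 4): bond type one-hot (single, double, triple,
# aromatic). Aromatic perceived bonds override their kekulized order.

NODE_FEATURE_DIM <- 27L
EDGE_FEATURE_DIM <- 4L

#' Featurize a molecule into a graph of node and edge vectors
#'
#' @param mol a `csmol_molecule`
#' @return a `csmol_graph`: list with `node_features` (n x 27 matrix),
#'   `edge_features` (m x 4 matrix), `adjacency` (data.frame `a1`, `a2`)
#' @export
featurize <- function(mol) {
  stopifnot(inherits(mol, "csmol_molecule"))
  n <- mol$n_heavy_atoms
  nf <- matrix(0, n, NODE_FEATURE_DIM)
  at <- match(mol$atoms$element, ATOM_VOCAB)
  at[is.na(at)] <- length(ATOM_VOCAB)  # explicit "other" slot, no silent drop
  nf[cbind(seq_len(n), at)] <- 1
  hy <- match(mol$atoms$hybridization, c("sp", "sp2", "sp3"))
  hy[is.na(hy)] <- 4L
  nf[cbind(seq_len(n), 13L + hy)] <- 1
  ch <- pmin(pmax(mol$atoms$charge, -2L), 2L) + 3L
  nf[cbind(seq_len(n), 17L + ch)] <- 1
  nf[, 23L] <- 1  # chiral tag: none (stereo not carried by the 2D parse)
  nf[, 26L] <- as.numeric(mol$atoms$in_ring)
  nf[, 27L] <- as.numeric(mol$atoms$aromatic)

  m <- mol$n_bonds
  ef <- matrix(0, m, EDGE_FEATURE_DIM)
  if (m > 0) {
    bt <- ifelse(mol$bonds$aromatic, 4L, pmin(mol$bonds$order, 3L))
    ef[cbind(seq_len(m), bt)] <- 1
  }
  structure(list(
    node_features = nf,
    edge_features = ef,
    adjacency = data.frame(a1 = mol$bonds$a1, a2 = mol$bonds$a2)
  ), class = "csmol_graph")
}
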