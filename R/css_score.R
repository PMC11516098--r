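# Built-in directional conformer-pair scorer.
#
# score(query -> reference) = shape term x feature-coverage term.
# Shape: rotation-invariant USR-style distance moments (mean, sigma,
# cube-root skew of heavy-atom distances to 4 reference points), compared
# as 1/(1 + mean |delta|). Coverage: the fraction of the REFERENCE's
# pharmacophore feature types that also occur in the query; normalizing
# by the reference makes the score directional, mimicking
# query-onto-reference superposition. Any scorer mapping conformer pairs
# to [0,1] may replace it.

#' USR-style distance-moment descriptor of one conformer
#'
#' Twelve rotation/translation-invariant moments: (mean, sigma, cube-root
#' skew) of heavy-atom distances to 4 reference points (centroid, atom
#' closest to centroid, atom farthest from centroid, atom farthest from
#' the latter).
#'
#' @param xyz coordinate matrix
#' @param heavy logical mask of heavy atoms
#' @return numeric vector of length 12
#' @export
usr_moments <- function(xyz, heavy = rep(TRUE, nrow(xyz))) {
  p <- xyz[heavy, , drop = FALSE]
  if (nrow(p) < 3) stop("degenerate geometry: fewer than 3 heavy atoms",
                        call. = FALSE)
  ctd <- colMeans(p)
  d_ctd <- sqrt(rowSums(sweep(p, 2, ctd)^2))
  cst <- p[which.min(d_ctd), ]
  fct <- p[which.max(d_ctd), ]
  d_fct <- sqrt(rowSums(sweep(p, 2, fct)^2))
  ftf <- p[which.max(d_fct), ]
  refs <- rbind(ctd, cst, fct, ftf)
  out <- numeric(0)
  for (i in 1:4) {
    d <- sqrt(rowSums(sweep(p, 2, refs[i, ])^2))
    mu <- mean(d)
    s2 <- mean((d - mu)^2)
    m3 <- mean((d - mu)^3)
    out <- c(out, mu, sqrt(s2), sign(m3) * abs(m3)^(1 / 3))
  }
  out
}

#' Score one query conformer against one reference conformer
#'
#' @param query_conf,ref_conf lists with `xyz` (coordinates), `heavy`
#'   (logical mask) and `features` (character vector of pharmacophore
#'   types of the parent molecule)
#' @return directional similarity in `[0, 1]`
#' @export
score_pair <- function(query_conf, ref_conf) {
  mq <- usr_moments(query_conf$xyz, query_conf$heavy)
  mr <- usr_moments(ref_conf$xyz, ref_conf$heavy)
  shape <- 1 / (1 + mean(abs(mq - mr)))
  ref_feats <- ref_conf$features
  coverage <- if (length(ref_feats) == 0) 1 else
    mean(ref_feats %in% query_conf$features)
  min(max(shape * coverage, 0), 1)
}

#' Score a query ensemble against a reference ensemble
#'
#' @param query,ref `csmol_ensemble` objects built under the same scheme,
#'   each carrying a `features` field (see [attach_features()])
#' @return a `csmol_pair_matrix`: `query_id`, `reference_id`, `scheme`,
#'   `scores` (rows = query conformers, cols = reference conformers)
#' @export
score_ensembles <- function(query, ref) {
  stopifnot(inherits(query, "csmol_ensemble"), inherits(ref, "csmol_ensemble"))
  if (!identical(query$scheme, ref$scheme)) {
    stop("scheme mismatch: '", query$scheme, "' vs '", ref$scheme, "'",
         call. = FALSE)
  }
  qh <- query$elements != "H"; rh <- ref$elements != "H"
  qm <- lapply(query$conformers, function(cf) usr_moments(cf$xyz, qh))
  rm_ <- lapply(ref$conformers, function(cf) usr_moments(cf$xyz, rh))
  cov_qr <- if (length(ref$features) == 0) 1 else
    mean(ref$features %in% query$features)
  scores <- matrix(0, length(qm), length(rm_))
  for (i in seq_along(qm)) {
    for (j in seq_along(rm_)) {
      shape <- 1 / (1 + mean(abs(qm[[i]] - rm_[[j]])))
      scores[i, j] <- min(max(shape * cov_qr, 0), 1)
    }
  }
  structure(list(
    query_id = query$molecule_id, reference_id = ref$molecule_id,
    scheme = query$scheme, scores = scores
  ), class = "csmol_pair_matrix")
}

#' Attach pharmacophore feature types to an ensemble
#'
#' @param ens a `csmol_ensemble`
#' @param mol the parent `csmol_molecule`
#' @export
attach_features <- function(ens, mol) {
  ens$features <- pharmacophore_types(mol)
  ens
}
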