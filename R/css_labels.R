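# Raw and advanced CSS descriptors for ordered molecule pairs.
#
# Raw (per direction, per scheme): matrix max/min of the ensemble-vs-
# ensemble score matrix -> Global_MAX, Global_MIN, Near_MAX, Near_MIN.
# Advanced (per direction): MaxSim = max of the four raw values,
# MaxDistance = min, MaxOverlap = (MaxSim + MaxDistance)/2,
# MaxAggregation = (Global_MAX + Near_MAX)/2. The Cross* family averages
# each descriptor over the two directions and is symmetric by
# construction.

CSS_COLUMNS <- c(
  "smiles_a", "smiles_b",
  "Global_MAX_ab", "Global_MIN_ab", "Near_MAX_ab", "Near_MIN_ab",
  "Global_MAX_ba", "Global_MIN_ba", "Near_MAX_ba", "Near_MIN_ba",
  "MaxSim", "MaxDistance", "MaxOverlap", "MaxAggregation",
  "CrossSim", "CrossDistance", "CrossOverlap", "CrossAggregation", "MCS"
)

#' Reduce a pair of score matrices to raw CSS descriptors (one direction)
#'
#' @param mat_global,mat_near `csmol_pair_matrix` objects for the global
#'   and near-native schemes of the same ordered pair
#' @return named list `Global_MAX`, `Global_MIN`, `Near_MAX`, `Near_MIN`
#' @export
reduce_raw <- function(mat_global, mat_near) {
  if (length(mat_global$scores) == 0 || length(mat_near$scores) == 0) {
    stop("empty score matrix", call. = FALSE)
  }
  list(
    Global_MAX = max(mat_global$scores), Global_MIN = min(mat_global$scores),
    Near_MAX = max(mat_near$scores), Near_MIN = min(mat_near$scores)
  )
}

#' Advanced CSS descriptors from the two directional raw sets
#'
#' @param raw_ab,raw_ba raw descriptor lists from [reduce_raw()] for the
#'   A-to-B and B-to-A directions
#' @return named list with the A-to-B `Max*` family and the symmetric
#'   `Cross*` family
#' @export
advanced_descriptors <- function(raw_ab, raw_ba) {
  adv <- function(r) {
    v <- c(r$Global_MAX, r$Global_MIN, r$Near_MAX, r$Near_MIN)
    ms <- max(v); md <- min(v)
    list(MaxSim = ms, MaxDistance = md, MaxOverlap = (ms + md) / 2,
         MaxAggregation = (r$Global_MAX + r$Near_MAX) / 2)
  }
  ab <- adv(raw_ab); ba <- adv(raw_ba)
  c(ab, list(
    CrossSim = (ab$MaxSim + ba$MaxSim) / 2,
    CrossDistance = (ab$MaxDistance + ba$MaxDistance) / 2,
    CrossOverlap = (ab$MaxOverlap + ba$MaxOverlap) / 2,
    CrossAggregation = (ab$MaxAggregation + ba$MaxAggregation) / 2
  ))
}

#' Label molecule pairs with CSS descriptors end-to-end
#'
#' For every ordered pair: conformer generation, strain filtering, RMSD
#' clustering under both schemes, ensemble-vs-ensemble scoring in both
#' directions, reduction to raw and advanced descriptors, plus the
#' element-agnostic MCS similarity. Ensembles are built once per molecule
#' and cached. Deterministic for a fixed seed.
#'
#' @param library a list of `csmol_molecule` (or data.frame with `smiles`,
#'   `id`, parsed on the fly)
#' @param pairs data.frame with columns `id_a`, `id_b`
#' @param budget conformer search budget per molecule
#' @param seed integer seed passed to the conformer backend
#' @param backend conformer backend (see [generate_conformers()])
#' @return data.frame with the fixed label-table column order
#'   (`csmol::CSS_COLUMNS`) plus `id_a`, `id_b`
#' @export
label_pairs <- function(library, pairs, budget = 100, seed = 1,
                        backend = distgeom_backend) {
  if (is.data.frame(library)) {
    library <- Map(parse_molecule, library$smiles, library$id)
    names(library) <- vapply(library, `[[`, character(1), "id")
  } else if (is.null(names(library))) {
    names(library) <- vapply(library, `[[`, character(1), "id")
  }
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(ids, names(library))
  if (length(missing) > 0) {
    stop("pair ids not in library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sch_g <- ensemble_scheme("global")
  sch_n <- ensemble_scheme("near_native")
  cache <- new.env(parent = emptyenv())
  get_ens <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    mol <- library[[id]]
    ens <- tryCatch(
      generate_conformers(mol, budget = budget, seed = seed, backend = backend),
      error = function(e) stop("pair labeling failed for molecule '", id,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    ens <- attach_features(ens, mol)
    out <- list(
      global = rmsd_cluster(strain_filter(ens, sch_g), sch_g),
      near = rmsd_cluster(strain_filter(ens, sch_n), sch_n)
    )
    out$global$features <- ens$features
    out$near$features <- ens$features
    cache[[id]] <- out
    out
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ia <- pairs$id_a[i]; ib <- pairs$id_b[i]
    ea <- get_ens(ia); eb <- get_ens(ib)
    raw_ab <- reduce_raw(score_ensembles(ea$global, eb$global),
                         score_ensembles(ea$near, eb$near))
    raw_ba <- reduce_raw(score_ensembles(eb$global, ea$global),
                         score_ensembles(eb$near, ea$near))
    adv <- advanced_descriptors(raw_ab, raw_ba)
    mcs <- mcs_similarity(library[[ia]], library[[ib]])$similarity
    rows[[i]] <- data.frame(
      id_a = ia, id_b = ib,
      smiles_a = library[[ia]]$smiles, smiles_b = library[[ib]]$smiles,
      Global_MAX_ab = raw_ab$Global_MAX, Global_MIN_ab = raw_ab$Global_MIN,
      Near_MAX_ab = raw_ab$Near_MAX, Near_MIN_ab = raw_ab$Near_MIN,
      Global_MAX_ba = raw_ba$Global_MAX, Global_MIN_ba = raw_ba$Global_MIN,
      Near_MAX_ba = raw_ba$Near_MAX, Near_MIN_ba = raw_ba$Near_MIN,
      MaxSim = adv$MaxSim, MaxDistance = adv$MaxDistance,
      MaxOverlap = adv$MaxOverlap, MaxAggregation = adv$MaxAggregation,
      CrossSim = adv$CrossSim, CrossDistance = adv$CrossDistance,
      CrossOverlap = adv$CrossOverlap, CrossAggregation = adv$CrossAggregation,
      MCS = mcs, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write a CSS label table with the fixed, versioned column order
#'
#' @param labels data.frame from [label_pairs()] or
#'   [gen_surrogate_labels()]
#' @param path output CSV path
#' @export
write_label_csv <- function(labels, path) {
  extra <- setdiff(names(labels), CSS_COLUMNS)
  write.csv(labels[, c(extra, CSS_COLUMNS)], path, row.names = FALSE,
            quote = FALSE)
}

#' Read a CSS label table
#' @param path CSV path
#' @export
read_label_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
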