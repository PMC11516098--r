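# Training-dataset construction: region classification of labeled pairs
# (dense / sparse / analogous in the MCS-vs-CSS plane), quota sampling at
# the 0.30:0.65:0.05 composition, positive-sample enrichment, scaffold
# splitting, and SMILES-randomization augmentation.

#' Sampler configuration
#'
#' @param region_ratios dense/sparse/analogous composition (must sum to 1)
#' @param positive_threshold MaxSim cutoff defining positives (default 0.6)
#' @param analogous_mcs_threshold MCS cutoff for the analogous region
#' @param smiles_randomize_p probability of emitting a randomized SMILES
#' @param seed integer seed
#' @export
sampler_config <- function(region_ratios = c(dense = 0.30, sparse = 0.65,
                                             analogous = 0.05),
                           positive_threshold = 0.6,
                           analogous_mcs_threshold = 0.6,
                           smiles_randomize_p = 0.9,
                           seed = 1) {
  stopifnot(all(region_ratios >= 0),
            abs(sum(region_ratios) - 1) < 1e-9,
            positive_threshold > 0, positive_threshold < 1,
            analogous_mcs_threshold > 0, analogous_mcs_threshold < 1)
  list(region_ratios = region_ratios,
       positive_threshold = positive_threshold,
       analogous_mcs_threshold = analogous_mcs_threshold,
       smiles_randomize_p = smiles_randomize_p,
       seed = seed)
}

#' Fit the dense-region density model
#'
#' A 2D Gaussian over (MCS, MaxSim) fitted to a calibration sample of
#' labeled pairs; the Mahalanobis radius `d0` is set so that ~`dense_target`
#' of the non-analogous calibration points classify as dense.
#'
#' @param calibration data.frame with `MCS` and `MaxSim` columns
#' @param cfg a [sampler_config()]
#' @param dense_target calibration dense fraction (default 0.30)
#' @return list `center`, `cov`, `d0`
#' @export
fit_density_model <- function(calibration, cfg = sampler_config(),
                              dense_target = 0.30) {
  x <- cbind(calibration$MCS, calibration$MaxSim)
  analog <- calibration$MCS >= cfg$analogous_mcs_threshold &
    calibration$MaxSim >= cfg$positive_threshold
  x <- x[!analog, , drop = FALSE]
  if (nrow(x) < 10) stop("calibration sample too small", call. = FALSE)
  ctr <- colMeans(x)
  cv <- cov(x)
  if (det(cv) < 1e-12) cv <- cv + diag(1e-8, 2)
  d <- mahalanobis(x, ctr, cv)
  list(center = ctr, cov = cv, d0 = unname(quantile(d, dense_target)))
}

#' Classify a labeled pair into its sampling region
#'
#' Analogous iff `MCS >= analogous_mcs_threshold` and
#' `MaxSim >= positive_threshold`; otherwise dense iff the (MCS, MaxSim)
#' point lies within the calibrated Mahalanobis radius of the density
#' model; else sparse.
#'
#' @param rec one-row data.frame (or list) with `MCS` and `MaxSim`
#' @param cfg a [sampler_config()]
#' @param density_model from [fit_density_model()]
#' @return `"dense"`, `"sparse"` or `"analogous"`
#' @export
classify_region <- function(rec, cfg, density_model = NULL) {
  mcs <- rec$MCS; ms <- rec$MaxSim
  if (any(is.na(c(mcs, ms)))) stop("record lacks MCS/MaxSim", call. = FALSE)
  analog <- mcs >= cfg$analogous_mcs_threshold & ms >= cfg$positive_threshold
  out <- rep(NA_character_, length(mcs))
  out[analog] <- "analogous"
  rest <- which(!analog)
  if (length(rest) > 0) {
    if (is.null(density_model)) stop("density model required", call. = FALSE)
    d <- mahalanobis(cbind(mcs[rest], ms[rest]),
                     density_model$center, density_model$cov)
    out[rest] <- ifelse(d <= density_model$d0, "dense", "sparse")
  }
  out
}

#' Sample labeled pairs at the configured region composition
#'
#' Draws unordered candidate pairs from the library, labels them with
#' `labeler`, classifies regions (density model fitted on the first
#' chunk), and fills per-region quotas `n_pairs * region_ratios`. Every
#' selected pair is also emitted in swapped order with the directional
#' columns exchanged. When a quota cannot be filled the composition
#' achieved is recorded in the manifest and a warning is raised.
#'
#' @param library data.frame from [gen_library()] (needs `id`)
#' @param n_pairs number of unordered pairs to select
#' @param cfg a [sampler_config()]
#' @param labeler function(pairs df) -> label table (e.g. a closure over
#'   [gen_surrogate_labels()] or [label_pairs()])
#' @param chunk_size candidate pairs labeled per round
#' @return the labeled pair table with a `region` column, both pair
#'   orders; manifest in `attr(, "manifest")`
#' @export
sample_pairs <- function(library, n_pairs, cfg = sampler_config(),
                         labeler, chunk_size = max(2000L, 2L * n_pairs)) {
  n <- nrow(library)
  if (n < 2) stop("library must contain at least 2 molecules", call. = FALSE)
  rng <- new_rng(cfg$seed)
  quota <- round(n_pairs * cfg$region_ratios)
  quota[1] <- n_pairs - sum(quota[-1])  # rounding: totals must match
  all_pairs <- utils::combn(n, 2)
  n_all <- ncol(all_pairs)
  order_all <- rng_sample(rng, n_all)   # seeded scan order over all pairs
  filled <- setNames(integer(3), names(quota))
  picked <- list()
  model <- NULL
  pos <- 1L
  while (pos <= n_all && any(filled < quota)) {
    take <- order_all[pos:min(pos + chunk_size - 1L, n_all)]
    pos <- pos + chunk_size
    cand <- data.frame(id_a = library$id[all_pairs[1, take]],
                       id_b = library$id[all_pairs[2, take]],
                       stringsAsFactors = FALSE)
    lab <- labeler(cand)
    if (is.null(model)) model <- fit_density_model(lab, cfg)
    region <- classify_region(lab, cfg, model)
    for (r in seq_len(nrow(lab))) {
      rg <- region[r]
      if (filled[rg] < quota[rg]) {
        filled[rg] <- filled[rg] + 1L
        lab_r <- lab[r, , drop = FALSE]
        lab_r$region <- rg
        picked[[length(picked) + 1L]] <- lab_r
      }
    }
  }
  if (any(filled < quota)) {
    warning("sampler could not reach the requested composition: ",
            paste(sprintf("%s %d/%d", names(quota), filled, quota),
                  collapse = ", "))
  }
  out <- do.call(rbind, picked)
  out <- rbind(out, swap_pair_rows(out))
  rownames(out) <- NULL
  attr(out, "manifest") <- list(requested = as.list(quota),
                                achieved = as.list(filled),
                                seed = cfg$seed)
  out
}

# Swapped-order duplicate of a label table: ids/smiles exchanged, the
# directional raw and Max* columns recomputed for the reversed direction,
# Cross* unchanged.
swap_pair_rows <- function(lab) {
  sw <- lab
  sw$id_a <- lab$id_b; sw$id_b <- lab$id_a
  sw$smiles_a <- lab$smiles_b; sw$smiles_b <- lab$smiles_a
  for (col in c("Global_MAX", "Global_MIN", "Near_MAX", "Near_MIN")) {
    sw[[paste0(col, "_ab")]] <- lab[[paste0(col, "_ba")]]
    sw[[paste0(col, "_ba")]] <- lab[[paste0(col, "_ab")]]
  }
  raw <- cbind(sw$Global_MAX_ab, sw$Global_MIN_ab, sw$Near_MAX_ab, sw$Near_MIN_ab)
  sw$MaxSim <- apply(raw, 1, max)
  sw$MaxDistance <- apply(raw, 1, min)
  sw$MaxOverlap <- (sw$MaxSim + sw$MaxDistance) / 2
  sw$MaxAggregation <- (sw$Global_MAX_ab + sw$Near_MAX_ab) / 2
  sw
}

#' Positive-sample enrichment
#'
#' The subset of a labeled pool with `MaxSim > positive_threshold` that is
#' not in the analogous region.
#'
#' @param pool labeled pair table with `MaxSim` and `region` columns
#' @param cfg a [sampler_config()]
#' @export
enrich_positives <- function(pool, cfg = sampler_config()) {
  pool[pool$MaxSim > cfg$positive_threshold & pool$region != "analogous", ,
       drop = FALSE]
}

#' High-similarity validation filter preset
#'
#' Pairs with `MaxSim >= threshold` outside the analogous region; used as
#' an additional held-out validation subset.
#'
#' @param pool labeled pair table with `region`
#' @param threshold MaxSim cutoff (default 0.75)
#' @export
filter_high_sim_nonanalogous <- function(pool, threshold = 0.75) {
  pool[pool$MaxSim >= threshold & pool$region != "analogous", , drop = FALSE]
}

#' Scaffold-based train/validation/test split
#'
#' Whole Murcko scaffolds are assigned to partitions: scaffolds are
#' visited in a seeded shuffle and each goes to the side (train vs test)
#' with the larger remaining deficit, followed by a small swap pass that
#' reduces any residual count imbalance; `validation_fraction` of the
#' training molecules (again whole scaffolds) is then carved out as
#' validation.
#'
#' @param library data.frame with `id` and `scaffold` columns
#' @param ratios `c(train, test)` molecule-count ratios (default 7:3)
#' @param seed integer seed
#' @param validation_fraction fraction of training molecules carved out
#' @return data.frame `id`, `scaffold`, `partition` with the scaffold ->
#'   partition manifest in `attr(, "manifest")`
#' @export
scaffold_split <- function(library, ratios = c(train = 0.7, test = 0.3),
                           seed = 1, validation_fraction = 0.1) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  scaffolds <- split(library$id, library$scaffold)
  if (length(scaffolds) < 2) {
    stop("fewer scaffolds (", length(scaffolds), ") than partitions",
         call. = FALSE)
  }
  rng <- new_rng(seed)
  ord <- rng_sample(rng, length(scaffolds))
  sizes <- vapply(scaffolds, length, integer(1))[ord]
  keys <- names(scaffolds)[ord]
  n <- nrow(library)
  target_train <- ratios[["train"]] * n
  assign_train <- logical(length(keys))
  cnt_train <- 0; cnt_test <- 0
  for (i in seq_along(keys)) {
    deficit_train <- target_train - cnt_train
    deficit_test <- (n - target_train) - cnt_test
    if (deficit_train >= deficit_test) {
      assign_train[i] <- TRUE; cnt_train <- cnt_train + sizes[i]
    } else {
      cnt_test <- cnt_test + sizes[i]
    }
  }
  # swap pass: move single scaffolds across while it reduces |imbalance|
  repeat {
    imb <- cnt_train - target_train
    best <- 0; best_i <- NA_integer_
    for (i in seq_along(keys)) {
      delta <- if (assign_train[i]) -sizes[i] else sizes[i]
      gain <- abs(imb) - abs(imb + delta)
      if (gain > best) { best <- gain; best_i <- i }
    }
    if (is.na(best_i)) break
    assign_train[best_i] <- !assign_train[best_i]
    cnt_train <- cnt_train + if (assign_train[best_i]) sizes[best_i] else -sizes[best_i]
  }
  part <- setNames(ifelse(assign_train, "train", "test"), keys)
  # validation carve-out: whole scaffolds, ~validation_fraction of train
  train_keys <- keys[assign_train]
  train_sizes <- sizes[assign_train]
  target_val <- validation_fraction * sum(train_sizes)
  cnt_val <- 0
  for (i in seq_along(train_keys)) {
    if (cnt_val + train_sizes[i] <= target_val + max(train_sizes) / 2 &&
        cnt_val < target_val) {
      part[train_keys[i]] <- "validation"
      cnt_val <- cnt_val + train_sizes[i]
    }
  }
  out <- data.frame(
    id = library$id, scaffold = library$scaffold,
    partition = unname(part[library$scaffold]),
    stringsAsFactors = FALSE
  )
  attr(out, "manifest") <- as.list(part)
  out
}

#' Partition of a molecule pair under a scaffold split
#'
#' Training-side membership includes the validation carve-out (validation
#' scaffolds are training scaffolds). Both members training-side ->
#' `"train"` (or `"validation"` when both are validation molecules);
#' exactly one training-side member -> `"cross"`; none -> `"test"`.
#'
#' @param split data.frame from [scaffold_split()]
#' @param id_a,id_b molecule id vectors
#' @return character vector of pair partitions
#' @export
pair_partition <- function(split, id_a, id_b) {
  p <- setNames(split$partition, split$id)
  pa <- p[id_a]; pb <- p[id_b]
  train_side <- function(x) x %in% c("train", "validation")
  n_train <- train_side(pa) + train_side(pb)
  ifelse(n_train == 1, "cross",
         ifelse(n_train == 0, "test",
                ifelse(pa == "validation" & pb == "validation",
                       "validation", "train")))
}

#' Randomize the atom ordering of a SMILES string
#'
#' With probability `p` returns a SMILES written from a random atom
#' permutation of the molecule (a valid non-canonical form); otherwise
#' returns the canonical SMILES. Either way the output re-canonicalizes
#' to the same molecule.
#'
#' @param smiles input SMILES
#' @param p randomization probability (default 0.9)
#' @param rng an internal RNG stream (from a seed); required
#' @return a SMILES string
#' @export
randomize_smiles <- function(smiles, p = 0.9, rng) {
  can <- ob_canonical(smiles)
  if (!nzchar(can)) stop("invalid SMILES: ", smiles, call. = FALSE)
  if (rng_unif(rng, 1) >= p) return(can)
  pm <- parse_molblock(ob_smiles_to_molblock(can))
  perm <- rng_sample(rng, pm$n_atoms)
  inv <- integer(pm$n_atoms); inv[perm] <- seq_len(pm$n_atoms)
  mb <- graph_to_molblock(
    pm$element[perm], pm$charge[perm],
    inv[pm$bond_a], inv[pm$bond_b], pm$bond_order,
    title = "randomized"
  )
  out <- ob_molblock_to_smiles(mb)
  if (!nzchar(out)) can else out
}
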