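# Deterministic synthetic fixtures: molecule libraries from a scaffold x
# substituent grammar, fast surrogate CSS labels for training-recovery
# experiments, planted screening benchmarks, bioactivity tables for the
# target-identification benchmark builder, and property tasks.

# Ring-system templates: one or two substitution slots marked {r}/{r2}.
FIXTURE_RING_TEMPLATES <- c(
  "c1ccc({r})cc1",                      # benzene, para
  "c1cc({r})ccc1{r2}",                  # benzene, 1,4-disubstituted
  "c1ccnc({r})c1",                      # pyridine
  "c1cc({r})cs1",                       # thiophene
  "c1cc({r})co1",                       # furan
  "c1cc({r})c[nH]1",                    # pyrrole
  "C1CCC({r})CC1",                      # cyclohexane
  "C1CCN({r})CC1",                      # piperidine (N-subst.)
  "O1CCN({r})CC1",                      # morpholine (N-subst.)
  "c1ccc2cc({r})ccc2c1",                # naphthalene
  "c1ccc2[nH]c({r})cc2c1",              # indole
  "c1ncc({r})cn1",                      # pyrimidine
  "c1ccc(-c2ccc({r})cc2)cc1",           # biphenyl
  "c1ccc(Cc2ccc({r})cc2)cc1",           # diphenylmethane
  "c1ccc(Oc2ccc({r})cc2)cc1",           # diphenyl ether
  "c1ccc(CCc2ccc({r})cc2)cc1",          # bibenzyl
  "c1ccc(NC(=O)c2ccc({r})cc2)cc1",      # benzanilide
  "c1ccc(-c2ccnc({r})c2)cc1",           # phenylpyridine
  "C1CCC(Cc2ccc({r})cc2)CC1",           # cyclohexylmethyl-benzene
  "c1cc(-c2ccc({r})cc2)cs1"             # phenylthiophene
)

# ring-bearing substituents use closure digits 8/9 so naive template
# substitution cannot collide with the templates' open digits 1/2
FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "CCO", "CO", "O", "OC", "N", "NC",
  "C(=O)O", "C(=O)N", "F", "Cl", "Br", "C#N", "CN(C)C", "S(C)(=O)=O",
  "N8CCOCC8", "c8ccco8", "C8CCCCC8", "n8cccc8"
)

fill_template <- function(tpl, r1, r2 = NULL) {
  out <- sub("{r}", r1, tpl, fixed = TRUE)
  if (grepl("{r2}", out, fixed = TRUE)) {
    if (is.null(r2)) return(NA_character_)
    out <- sub("{r2}", r2, out, fixed = TRUE)
  }
  out
}

#' Generate a deterministic synthetic molecule library
#'
#' Enumerates scaffold-template x substituent combinations from a drug-like
#' grammar, validity-checks and canonicalizes every SMILES, deduplicates,
#' and draws a seeded, scaffold-balanced subsample of `n_molecules`
#' (per-scaffold counts are capped so no single Murcko scaffold dominates).
#'
#' @param n_molecules library size
#' @param seed integer seed
#' @param templates,substituents grammar; defaults to the shipped grammar
#' @param max_per_scaffold cap on molecules sharing one Murcko scaffold
#'   (default `max(3, ceiling(n_molecules / 25))`)
#' @param family_size when set, builds a family-structured library
#'   instead: `ceiling(n/family_size)` templates each instantiated with
#'   `family_size` substituents, giving structural-analog families (used
#'   to emulate the analog content of real pair datasets)
#' @return data.frame `id`, `smiles` (canonical), `scaffold`, with the
#'   parsed molecules in `attr(, "molecules")`
#' @export
gen_library <- function(n_molecules = 50, seed = 1,
                        templates = FIXTURE_RING_TEMPLATES,
                        substituents = FIXTURE_SUBSTITUENTS,
                        max_per_scaffold = max(3L, ceiling(n_molecules / 25)),
                        family_size = NULL) {
  if (length(templates) == 0 || length(substituents) == 0) {
    stop("empty grammar", call. = FALSE)
  }
  rng <- new_rng(seed)
  if (!is.null(family_size)) {
    return(gen_library_families(n_molecules, family_size, rng,
                                templates, substituents))
  }
  cand <- character(0)
  for (tpl in templates) {
    if (grepl("{r2}", tpl, fixed = TRUE)) {
      for (r1 in substituents) for (r2 in substituents) {
        cand <- c(cand, fill_template(tpl, r1, r2))
      }
    } else {
      for (r1 in substituents) cand <- c(cand, fill_template(tpl, r1))
    }
  }
  cand <- unique(cand[!is.na(cand)])
  cand <- cand[rng_sample(rng, length(cand))]  # seeded shuffle
  mols <- list(); seen <- character(0)
  take <- integer(0)
  pos <- 0L
  # parse in blocks until the capped round-robin subsample is satisfied
  repeat {
    block_end <- min(pos + 4L * n_molecules, length(cand))
    while (pos < block_end) {
      pos <- pos + 1L
      m <- tryCatch(parse_molecule(cand[pos],
                                   id = sprintf("M%04d", length(mols) + 1L)),
                    error = function(e) NULL)
      if (is.null(m) || m$smiles %in% seen || m$n_heavy_atoms > 30) next
      seen <- c(seen, m$smiles)
      mols[[length(mols) + 1L]] <- m
    }
    scaffolds <- vapply(mols, `[[`, character(1), "scaffold_key")
    # scaffold-balanced, capped subsample: round-robin across scaffolds
    by_scaffold <- split(seq_along(mols), scaffolds)
    ord <- rng_eval(new_rng(seed + 1L),
                    function() sample.int(length(by_scaffold)))
    by_scaffold <- by_scaffold[ord]
    take <- integer(0)
    round_i <- 1L
    while (length(take) < n_molecules && round_i <= max_per_scaffold) {
      for (grp in by_scaffold) {
        if (length(grp) >= round_i && length(take) < n_molecules) {
          take <- c(take, grp[round_i])
        }
      }
      round_i <- round_i + 1L
    }
    if (length(take) >= n_molecules || pos >= length(cand)) break
  }
  if (length(take) < n_molecules) {
    stop("grammar produced only ", length(take), " molecules under the ",
         "scaffold cap; requested ", n_molecules, call. = FALSE)
  }
  mols <- mols[sort(take)]
  for (i in seq_along(mols)) mols[[i]]$id <- sprintf("M%04d", i)
  out <- data.frame(
    id = vapply(mols, `[[`, character(1), "id"),
    smiles = vapply(mols, `[[`, character(1), "smiles"),
    scaffold = vapply(mols, `[[`, character(1), "scaffold_key"),
    stringsAsFactors = FALSE
  )
  names(mols) <- out$id
  attr(out, "molecules") <- mols
  out
}

# Family-structured variant: each template contributes `family_size`
# analogs (single-slot instantiations; 2-slot templates get a fixed
# second substituent), so the pair set contains both close analogs and
# cross-family diversity.
gen_library_families <- function(n_molecules, family_size, rng,
                                 templates, substituents) {
  n_fam <- ceiling(n_molecules / family_size)
  tpl_ord <- templates[rng_sample(rng, length(templates))]
  if (n_fam > length(tpl_ord)) {
    stop("grammar has ", length(tpl_ord), " templates; need ", n_fam,
         " families", call. = FALSE)
  }
  mols <- list(); seen <- character(0)
  for (tpl in tpl_ord[seq_len(n_fam)]) {
    subs <- substituents[rng_sample(rng, length(substituents))]
    got <- 0L
    for (r1 in subs) {
      if (got >= family_size || length(mols) >= n_molecules) break
      smi <- fill_template(tpl, r1, r2 = "C")
      m <- tryCatch(parse_molecule(smi, sprintf("M%04d", length(mols) + 1L)),
                    error = function(e) NULL)
      if (is.null(m) || m$smiles %in% seen || m$n_heavy_atoms > 30) next
      seen <- c(seen, m$smiles)
      mols[[length(mols) + 1L]] <- m
      got <- got + 1L
    }
  }
  if (length(mols) < n_molecules) {
    stop("grammar produced only ", length(mols), " molecules; requested ",
         n_molecules, call. = FALSE)
  }
  out <- data.frame(
    id = vapply(mols, `[[`, character(1), "id"),
    smiles = vapply(mols, `[[`, character(1), "smiles"),
    scaffold = vapply(mols, `[[`, character(1), "scaffold_key"),
    stringsAsFactors = FALSE
  )
  names(mols) <- out$id
  attr(out, "molecules") <- mols
  out
}

# Fixed random-projection kernel over path fingerprints: the noise-free
# ground truth for surrogate labels. The projection seed is a constant so
# the kernel is the same function for every user seed.
.surrogate_projection <- function(nbits = 512L, k = 24L) {
  rng <- new_rng(987654321L)
  matrix(rng_norm(rng, k * nbits), k, nbits)
}

surrogate_kernel <- function(fps) {
  W <- .surrogate_projection(ncol(fps))
  Z <- fps %*% t(W)
  nz <- sqrt(rowSums(Z^2)); nz[nz == 0] <- 1
  Z <- Z / nz
  S <- Z %*% t(Z)           # cosine in projected space, in [-1, 1]
  (S + 1) / 2
}

#' Fast surrogate CSS labels with a known smooth ground truth
#'
#' Labels every given pair with a fixed random-projection kernel over
#' hashed path fingerprints (squashed to `[0, 1]`) plus bounded noise
#' `U(-0.02, 0.02)` on the raw descriptors; the advanced descriptors are
#' then computed exactly, so the label table satisfies the CSS algebra
#' identities by construction. Self-pairs have a noise-free kernel value
#' of 1.
#'
#' @param library data.frame from [gen_library()] (or with `id`, `smiles`)
#' @param pairs data.frame with `id_a`, `id_b`; when `NULL`, all unordered
#'   pairs are labeled
#' @param seed integer seed (noise only; the kernel itself is fixed)
#' @return data.frame in the label-table layout of [label_pairs()]
#' @export
gen_surrogate_labels <- function(library, pairs = NULL, seed = 1) {
  mols <- attr(library, "molecules")
  if (is.null(mols)) {
    mols <- Map(parse_molecule, library$smiles, library$id)
    names(mols) <- library$id
  }
  if (is.null(pairs)) {
    idx <- utils::combn(library$id, 2)
    pairs <- data.frame(id_a = idx[1, ], id_b = idx[2, ],
                        stringsAsFactors = FALSE)
  }
  fps <- t(vapply(mols, path_fingerprint, integer(512L)))
  K <- surrogate_kernel(fps)
  rownames(K) <- colnames(K) <- names(mols)
  rng <- new_rng(seed)
  n <- nrow(pairs)
  noise <- matrix(rng_unif(rng, 8L * n, -0.02, 0.02), n, 8L)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  base <- K[cbind(pairs$id_a, pairs$id_b)]
  nb_a <- vapply(mols[pairs$id_a], `[[`, integer(1), "n_bonds")
  nb_b <- vapply(mols[pairs$id_b], `[[`, integer(1), "n_bonds")
  asym <- 0.05 * tanh((nb_a - nb_b) / 10)  # query larger -> covers reference
  raw <- function(b, e1, e2, e3, e4) {
    g_max <- clamp(b + 0.05 + e1); g_min <- clamp(0.50 * b + e2)
    n_max <- clamp(0.90 * b + e3); n_min <- clamp(0.60 * b + e4)
    cbind(G_MAX = pmax(g_max, g_min), G_MIN = pmin(g_max, g_min),
          N_MAX = pmax(n_max, n_min), N_MIN = pmin(n_max, n_min))
  }
  r_ab <- raw(clamp(base + asym), noise[, 1], noise[, 2], noise[, 3], noise[, 4])
  r_ba <- raw(clamp(base - asym), noise[, 5], noise[, 6], noise[, 7], noise[, 8])
  adv <- function(r) {
    ms <- pmax(r[, 1], r[, 2], r[, 3], r[, 4])
    md <- pmin(r[, 1], r[, 2], r[, 3], r[, 4])
    cbind(MaxSim = ms, MaxDistance = md, MaxOverlap = (ms + md) / 2,
          MaxAggregation = (r[, "G_MAX"] + r[, "N_MAX"]) / 2)
  }
  a_ab <- adv(r_ab); a_ba <- adv(r_ba)
  mcs <- vapply(seq_len(n), function(i) {
    tanimoto(fps[pairs$id_a[i], ], fps[pairs$id_b[i], ])
  }, numeric(1))
  data.frame(
    id_a = pairs$id_a, id_b = pairs$id_b,
    smiles_a = library$smiles[match(pairs$id_a, library$id)],
    smiles_b = library$smiles[match(pairs$id_b, library$id)],
    Global_MAX_ab = r_ab[, 1], Global_MIN_ab = r_ab[, 2],
    Near_MAX_ab = r_ab[, 3], Near_MIN_ab = r_ab[, 4],
    Global_MAX_ba = r_ba[, 1], Global_MIN_ba = r_ba[, 2],
    Near_MAX_ba = r_ba[, 3], Near_MIN_ba = r_ba[, 4],
    MaxSim = a_ab[, 1], MaxDistance = a_ab[, 2],
    MaxOverlap = a_ab[, 3], MaxAggregation = a_ab[, 4],
    CrossSim = (a_ab[, 1] + a_ba[, 1]) / 2,
    CrossDistance = (a_ab[, 2] + a_ba[, 2]) / 2,
    CrossOverlap = (a_ab[, 3] + a_ba[, 3]) / 2,
    CrossAggregation = (a_ab[, 4] + a_ba[, 4]) / 2,
    MCS = mcs, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Planted-signal screening benchmark
#'
#' Builds one structural-analog family (a single scaffold template across
#' many substituents) as the active class, holds out `n_references` family
#' members as references, and draws decoys from the diverse grammar
#' excluding the active scaffold. Actives are near the references under
#' fingerprint similarity by construction.
#'
#' @param n_actives number of actives
#' @param n_decoys number of decoys
#' @param seed integer seed
#' @param n_references held-out reference molecules (default 2)
#' @param family_template scaffold template of the active family
#' @return list `references` (data.frame `id`, `smiles`), `library`
#'   (data.frame `id`, `smiles`, `scaffold`, `active`)
#' @export
gen_screening_benchmark <- function(n_actives = 10, n_decoys = 40, seed = 1,
                                    n_references = 2,
                                    family_template = "c1ccc(-c2ccc({r})cc2)cc1") {
  rng <- new_rng(seed)
  fam_smi <- unique(vapply(FIXTURE_SUBSTITUENTS, function(r)
    fill_template(family_template, r), character(1)))
  fam <- list()
  for (smi in fam_smi[rng_sample(rng, length(fam_smi))]) {
    m <- tryCatch(parse_molecule(smi, sprintf("A%03d", length(fam) + 1L)),
                  error = function(e) NULL)
    if (!is.null(m)) fam[[length(fam) + 1L]] <- m
  }
  fam_scaffolds <- vapply(fam, `[[`, character(1), "scaffold_key")
  core <- names(sort(table(fam_scaffolds), decreasing = TRUE))[1]
  fam <- fam[fam_scaffolds == core]
  need <- n_actives + n_references
  if (length(fam) < need) {
    stop("analog family has only ", length(fam), " members; need ", need,
         call. = FALSE)
  }
  fam <- fam[seq_len(need)]
  refs <- fam[seq_len(n_references)]
  actives <- fam[(n_references + 1):need]
  decoy_lib <- gen_library(n_decoys + 20L, seed = seed + 1L,
                           max_per_scaffold = max(12L, ceiling(n_decoys / 15)))
  decoy_keep <- decoy_lib$scaffold != core
  decoy_lib <- decoy_lib[decoy_keep, , drop = FALSE][seq_len(n_decoys), ]
  lib <- rbind(
    data.frame(id = vapply(actives, `[[`, character(1), "id"),
               smiles = vapply(actives, `[[`, character(1), "smiles"),
               scaffold = core, active = TRUE, stringsAsFactors = FALSE),
    data.frame(id = decoy_lib$id, smiles = decoy_lib$smiles,
               scaffold = decoy_lib$scaffold, active = FALSE,
               stringsAsFactors = FALSE)
  )
  list(
    references = data.frame(
      id = vapply(refs, `[[`, character(1), "id"),
      smiles = vapply(refs, `[[`, character(1), "smiles"),
      stringsAsFactors = FALSE),
    library = lib
  )
}

#' Synthetic bioactivity table for the target-identification builder
#'
#' Emits (ligand, target, affinity) rows with per-ligand activity-entry
#' counts and targets organized so that same-scaffold ligands share
#' targets; includes ligands on both sides of every curation filter.
#'
#' @param library data.frame from [gen_library()]
#' @param n_targets number of distinct targets
#' @param seed integer seed
#' @return data.frame `ligand_id`, `smiles`, `target`, `affinity_value`,
#'   `affinity_unit`, `n_entries`
#' @export
gen_bioactivity_table <- function(library, n_targets = 20, seed = 1) {
  rng <- new_rng(seed)
  targets <- sprintf("T%03d", seq_len(n_targets))
  scaff <- factor(library$scaffold)
  base_t <- (as.integer(scaff) - 1L) %% n_targets + 1L
  rows <- list()
  for (i in seq_len(nrow(library))) {
    k <- 1L + (rng_int(rng, 4L) - 1L)       # 1..4 targets per ligand
    tset <- unique(c(base_t[i],
                     ((base_t[i] + seq_len(k) - 1L) %% n_targets) + 1L))
    n_entries <- 150L + rng_int(rng, 400L)  # straddles the 300-entry filter
    for (tt in tset) {
      aff <- 10 ^ rng_unif(rng, 1, 0, 5)    # 1 nM .. 100 uM
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_id = library$id[i], smiles = library$smiles[i],
        target = targets[tt], affinity_value = aff, affinity_unit = "nM",
        n_entries = n_entries, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Synthetic property task over a fixture library
#'
#' The label is a smooth function of the fixed fingerprint projection used
#' by the surrogate kernel: regression targets are the first projection
#' coordinate plus noise; classification thresholds it at the median.
#'
#' @param library data.frame from [gen_library()]
#' @param task_type `"classification"` or `"regression"`
#' @param seed integer seed
#' @param noise_sd Gaussian label noise (regression scale)
#' @return data.frame `id`, `smiles`, `label`
#' @export
gen_property_task <- function(library, task_type = c("classification", "regression"),
                              seed = 1, noise_sd = 0.05) {
  task_type <- match.arg(task_type)
  mols <- attr(library, "molecules")
  if (is.null(mols)) {
    mols <- Map(parse_molecule, library$smiles, library$id)
  }
  fps <- t(vapply(mols, path_fingerprint, integer(512L)))
  W <- .surrogate_projection(512L)
  z <- scale(fps %*% W[1, ])[, 1]
  rng <- new_rng(seed)
  y <- z + rng_norm(rng, length(z)) * noise_sd
  if (task_type == "classification") y <- as.integer(y > stats::median(y))
  data.frame(id = library$id, smiles = library$smiles, label = y,
             stringsAsFactors = FALSE)
}
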