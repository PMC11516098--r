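# Encoding-space similarity, ranking metrics for early recognition
# (BEDROC, AUROC, enrichment factor), zero-shot screening and target
# identification, the bioactivity-benchmark curation filters, and
# fingerprint baselines.

#' Cosine similarity of two encoding vectors
#' @param a,b numeric vectors of equal length
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Pearson similarity of two encoding vectors
#' @param a,b numeric vectors of equal length >= 2
#' @export
pearson_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need length >= 2", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("Pearson similarity undefined for a constant vector", call. = FALSE)
  }
  cov(a, b) / (sd(a) * sd(b))
}

#' BEDROC early-recognition metric
#'
#' The rank-sum RIE statistic rescaled to `[0, 1]` by its analytic
#' minimum and maximum at the given (n, N, alpha), so that actives ranked
#' 1..n give exactly 1 and actives ranked last give exactly 0.
#'
#' @param ranks ranks of the actives (1 = best) in a ranking of N items
#' @param n number of actives
#' @param N library size
#' @param alpha early-recognition exponent (160.9 weights ~ the top 1%)
#' @export
bedroc <- function(ranks, n, N, alpha = 160.9) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  stopifnot(length(ranks) == n, n >= 1, n <= N,
            all(ranks >= 1), all(ranks <= N), !anyDuplicated(ranks))
  s <- sum(exp(-alpha * ranks / N))
  q <- exp(-alpha / N)
  geo <- function(first) first * (1 - q^n) / (1 - q)  # sum of n terms ratio q
  s_max <- geo(q)                 # ranks 1..n
  s_min <- geo(q^(N - n + 1))     # ranks N-n+1..N
  (s - s_min) / (s_max - s_min)
}

# closed-form expectation of the scaled RIE under uniform random ranking
bedroc_random_mean <- function(n, N, alpha = 160.9) {
  q <- exp(-alpha / N)
  e_one <- q * (1 - q^N) / (N * (1 - q))  # E e^{-alpha r/N}, r uniform 1..N
  s_mean <- n * e_one
  geo <- function(first) first * (1 - q^n) / (1 - q)
  (s_mean - geo(q^(N - n + 1))) / (geo(q) - geo(q^(N - n + 1)))
}

#' Enrichment factor at a top fraction
#'
#' @inheritParams bedroc
#' @param fraction top fraction of the ranking (default 0.01)
#' @export
enrichment_factor <- function(ranks, n, N, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  top <- ceiling(fraction * N)
  (sum(ranks <= top) / top) / (n / N)
}

#' AUROC from scores and binary labels (rank/Mann-Whitney form)
#' @param scores numeric vector (higher = more active-like)
#' @param active logical vector
#' @export
auroc <- function(scores, active) {
  n1 <- sum(active); n0 <- sum(!active)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[active]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screening configuration
#'
#' @param metric `"cosine"`, `"pearson"`, or a head name (requires a
#'   trained checkpoint)
#' @param bedroc_alpha BEDROC exponent (default 160.9, ~ EF1%)
#' @param ef_fraction enrichment-factor fraction (default 0.01)
#' @export
screening_config <- function(metric = "cosine", bedroc_alpha = 160.9,
                             ef_fraction = 0.01) {
  stopifnot(bedroc_alpha > 0, ef_fraction > 0, ef_fraction < 1)
  list(metric = metric, bedroc_alpha = bedroc_alpha,
       ef_fraction = ef_fraction, multi_reference = "max")
}

similarity_matrix <- function(lib_enc, ref_enc, metric, model = NULL) {
  if (metric %in% c("cosine", "pearson")) {
    f <- if (metric == "cosine") cosine_similarity else pearson_similarity
    outer(seq_len(nrow(lib_enc)), seq_len(nrow(ref_enc)),
          Vectorize(function(i, j) f(lib_enc[i, ], ref_enc[j, ])))
  } else if (metric %in% HEAD_TARGETS) {
    if (is.null(model)) {
      stop("metric '", metric, "' requires a trained checkpoint", call. = FALSE)
    }
    sapply(seq_len(nrow(ref_enc)), function(j) {
      project(model$heads[[metric]], lib_enc,
              ref_enc[rep(j, nrow(lib_enc)), , drop = FALSE])
    })
  } else {
    stop("unknown metric '", metric, "'", call. = FALSE)
  }
}

#' Zero-shot virtual screening
#'
#' Scores each library molecule as the maximum similarity to any
#' reference, ranks by descending score (ties broken by stable molecule
#' id order), and reports BEDROC, AUROC and the enrichment factor.
#'
#' @param ref_enc matrix of reference encodings (rows = references)
#' @param lib_enc matrix of library encodings, rownames = molecule ids
#' @param active logical vector per library molecule
#' @param cfg a [screening_config()]
#' @param model optional checkpoint when `metric` is a head name
#' @return list `scores` (data.frame id, score, active, rank), `bedroc`,
#'   `auroc`, `ef`
#' @export
screen <- function(ref_enc, lib_enc, active, cfg = screening_config(),
                   model = NULL) {
  if (is.null(dim(ref_enc))) ref_enc <- matrix(ref_enc, 1)
  stopifnot(nrow(ref_enc) >= 1, length(active) == nrow(lib_enc))
  sims <- similarity_matrix(lib_enc, ref_enc, cfg$metric, model)
  score <- apply(sims, 1, max)
  ids <- rownames(lib_enc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(lib_enc)))
  ord <- order(-score, ids)  # stable tie policy: ascending id
  rank_of <- integer(length(score)); rank_of[ord] <- seq_along(ord)
  n <- sum(active); N <- length(active)
  list(
    scores = data.frame(id = ids, score = score, active = active,
                        rank = rank_of, stringsAsFactors = FALSE),
    bedroc = bedroc(rank_of[active], n, N, cfg$bedroc_alpha),
    auroc = auroc(score, active),
    ef = enrichment_factor(rank_of[active], n, N, cfg$ef_fraction)
  )
}

#' Zero-shot target identification
#'
#' Each target is scored as the maximum similarity between the query and
#' that target's ligands; AUROC/BEDROC are computed over targets with the
#' query's annotated targets as positives.
#'
#' @param query_enc encoding vector of the query ligand
#' @param lib_enc matrix of library-ligand encodings, rownames = ligand ids
#' @param ligand_targets named list: ligand id -> character vector of
#'   target ids
#' @param true_targets the query's annotated targets
#' @param cfg a [screening_config()]
#' @param model optional checkpoint for head-name metrics
#' @return list `target_scores` (data.frame), `auroc`, `bedroc`
#' @export
target_id <- function(query_enc, lib_enc, ligand_targets, true_targets,
                      cfg = screening_config(), model = NULL) {
  stopifnot(length(ligand_targets) == nrow(lib_enc))
  all_targets <- sort(unique(unlist(ligand_targets)))
  if (!any(true_targets %in% all_targets)) {
    stop("query has no annotated target in the library", call. = FALSE)
  }
  sims <- similarity_matrix(lib_enc, matrix(query_enc, 1), cfg$metric, model)
  lig_score <- sims[, 1]
  tgt_score <- vapply(all_targets, function(t) {
    max(lig_score[vapply(ligand_targets, function(ts) t %in% ts, logical(1))])
  }, numeric(1))
  pos <- all_targets %in% true_targets
  ord <- order(-tgt_score, all_targets)
  rank_of <- integer(length(tgt_score)); rank_of[ord] <- seq_along(ord)
  list(
    target_scores = data.frame(target = all_targets, score = tgt_score,
                               true_target = pos, rank = rank_of,
                               stringsAsFactors = FALSE),
    auroc = auroc(tgt_score, pos),
    bedroc = bedroc(rank_of[pos], sum(pos), length(pos), cfg$bedroc_alpha)
  )
}

AFFINITY_UNIT_NM <- c(pM = 1e-3, nM = 1, uM = 1e3, "µM" = 1e3,
                      mM = 1e6, M = 1e9)

#' Build a target-identification benchmark from a bioactivity table
#'
#' Curation stages, in order: (1) keep query ligands with more than
#' `min_entries` activity entries and at least `min_heavy_atoms` heavy
#' atoms; (2) drop (query, target) links with affinity above
#' `max_affinity_nM`; (3) for each query, drop library ligands with MCS
#' similarity above `max_mcs` to the query; (4) the refined subset keeps
#' queries with more than `min_targets` remaining targets.
#'
#' @param table data.frame with `ligand_id`, `smiles`, `target`,
#'   `affinity_value`, `affinity_unit`, `n_entries`
#' @param molecules optional named list of parsed `csmol_molecule`
#' @param min_entries,min_heavy_atoms,max_affinity_nM,max_mcs,min_targets
#'   stage thresholds (defaults 300, 12, 1e4 = 10 uM, 0.5, 70)
#' @return list `queries` (per-query target sets and allowed library
#'   ligands), `refined_ids`, `manifest` (counts per stage)
#' @export
build_target_benchmark <- function(table, molecules = NULL,
                                   min_entries = 300, min_heavy_atoms = 12,
                                   max_affinity_nM = 1e4, max_mcs = 0.5,
                                   min_targets = 70) {
  if (any(!table$affinity_unit %in% names(AFFINITY_UNIT_NM))) {
    bad <- unique(table$affinity_unit[!table$affinity_unit %in%
                                        names(AFFINITY_UNIT_NM)])
    stop("unconvertible affinity units: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table$affinity_nM <- table$affinity_value *
    AFFINITY_UNIT_NM[table$affinity_unit]
  lig <- unique(table[, c("ligand_id", "smiles", "n_entries")])
  if (is.null(molecules)) {
    molecules <- Map(parse_molecule, lig$smiles, lig$ligand_id)
    names(molecules) <- lig$ligand_id
  }
  heavy <- vapply(molecules[lig$ligand_id], `[[`, integer(1), "n_heavy_atoms")
  # stage 1: query eligibility
  q_ids <- lig$ligand_id[lig$n_entries > min_entries &
                           heavy >= min_heavy_atoms]
  manifest <- list(n_ligands = nrow(lig), stage1_queries = length(q_ids))
  # stage 2: affinity filter on links
  keep_links <- table$affinity_nM <= max_affinity_nM
  tbl2 <- table[keep_links, , drop = FALSE]
  manifest$stage2_links <- nrow(tbl2)
  queries <- list()
  for (q in q_ids) {
    tset <- unique(tbl2$target[tbl2$ligand_id == q])
    if (length(tset) == 0) next
    # stage 3: drop similar library ligands
    others <- setdiff(lig$ligand_id, q)
    sims <- vapply(others, function(o) {
      mcs_similarity(molecules[[q]], molecules[[o]])$similarity
    }, numeric(1))
    allowed <- others[sims <= max_mcs]
    remaining <- unique(tbl2$target[tbl2$ligand_id %in% allowed])
    queries[[q]] <- list(query = q, true_targets = tset,
                         library = allowed,
                         n_targets_remaining = length(intersect(tset, remaining)),
                         n_library_targets = length(remaining))
  }
  manifest$stage3_queries <- length(queries)
  refined <- names(queries)[vapply(queries, function(x)
    x$n_library_targets > min_targets, logical(1))]
  manifest$stage4_refined <- length(refined)
  list(queries = queries, refined_ids = refined, manifest = manifest)
}

FP_METRICS <- c("Tanimoto", "Dice", "Sokal", "Cosine", "Russel",
                "Kulczynski", "McConnaughey", "Tversky")

#' Fingerprint-baseline similarity
#'
#' @param a,b `csmol_molecule` objects
#' @param fp_name `"path"` (in-package hashed path fingerprint) or an
#'   OpenBabel fingerprint (`"FP2"`, `"FP3"`, `"FP4"`, `"MACCS"`)
#' @param metric one of `r paste(FP_METRICS, collapse=", ")`
#' @param alpha Tversky weight on the first molecule's private features
#' @return similarity in `[0, 1]` (McConnaughey is affinely rescaled from
#'   `[-1, 1]`)
#' @export
fingerprint_baseline <- function(a, b, fp_name = "path",
                                 metric = "Tanimoto", alpha = 0.5) {
  get_fp <- function(m) {
    if (fp_name == "path") return(path_fingerprint(m))
    if (fp_name %in% c("FP2", "FP3", "FP4", "MACCS")) {
      return(ob_fingerprint(ob_smiles_to_molblock(m$smiles), fp_name))
    }
    stop("unknown fingerprint '", fp_name, "'", call. = FALSE)
  }
  if (!metric %in% FP_METRICS) {
    stop("unknown similarity metric '", metric, "'", call. = FALSE)
  }
  fa <- get_fp(a); fb <- get_fp(b)
  n <- length(fa)
  c_ <- sum(fa & fb)
  a_ <- sum(fa & !fb)
  b_ <- sum(!fa & fb)
  safe <- function(num, den) if (den == 0) 0 else num / den
  switch(metric,
    Tanimoto = safe(c_, a_ + b_ + c_),
    Dice = safe(2 * c_, 2 * c_ + a_ + b_),
    Sokal = safe(c_, c_ + 2 * a_ + 2 * b_),
    Cosine = safe(c_, sqrt((c_ + a_) * (c_ + b_))),
    Russel = c_ / n,
    Kulczynski = 0.5 * (safe(c_, c_ + a_) + safe(c_, c_ + b_)),
    McConnaughey = (safe(c_^2 - a_ * b_, (c_ + a_) * (c_ + b_)) + 1) / 2,
    Tversky = safe(c_, c_ + alpha * a_ + (1 - alpha) * b_)
  )
}
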