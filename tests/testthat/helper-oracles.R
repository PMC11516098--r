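# Shared fixtures and independent oracles for the test suite.

# small molecule cache so repeated tests don't re-parse
.mol_cache <- new.env(parent = emptyenv())
mol <- function(smiles, id = smiles) {
  key <- paste0(smiles, "|", id)
  if (is.null(.mol_cache[[key]])) {
    .mol_cache[[key]] <- parse_molecule(smiles, id)
  }
  .mol_cache[[key]]
}

# --- independent MCS oracle: exhaustive common-connected-edge-subgraph ---
# Enumerates subsets of the smaller molecule's bonds from largest to
# smallest, keeps connected ones, and tests embeddability into the other
# molecule by naive backtracking. Shares no code with mcs_similarity().

subset_connected <- function(bonds_a1, bonds_a2, subset) {
  if (length(subset) <= 1) return(TRUE)
  atoms <- unique(c(bonds_a1[subset], bonds_a2[subset]))
  seen <- bonds_a1[subset[1]]
  seen <- unique(c(seen, bonds_a2[subset[1]]))
  used <- rep(FALSE, length(subset)); used[1] <- TRUE
  repeat {
    grew <- FALSE
    for (k in seq_along(subset)) {
      if (used[k]) next
      e <- subset[k]
      if (bonds_a1[e] %in% seen || bonds_a2[e] %in% seen) {
        seen <- unique(c(seen, bonds_a1[e], bonds_a2[e]))
        used[k] <- TRUE; grew <- TRUE
      }
    }
    if (!grew) break
  }
  all(used)
}

# can the bond subset of `a` (edge indices) be embedded into `b`?
# wildcard atom matching; bonds must agree on ring membership
embeds_into <- function(a, subset, b) {
  asub1 <- a$bonds$a1[subset]; asub2 <- a$bonds$a2[subset]
  aring <- a$bonds$in_ring[subset]
  m <- length(subset)
  assign_next <- function(k, amap, used_b) {
    if (k > m) return(TRUE)
    for (l in seq_len(b$n_bonds)) {
      if (used_b[l]) next
      if (b$bonds$in_ring[l] != aring[k]) next
      for (ori in 1:2) {
        x <- if (ori == 1) b$bonds$a1[l] else b$bonds$a2[l]
        y <- if (ori == 1) b$bonds$a2[l] else b$bonds$a1[l]
        u <- asub1[k]; v <- asub2[k]
        ok_u <- is.na(amap[u]) && !(x %in% amap) || (!is.na(amap[u]) && amap[u] == x)
        ok_v <- is.na(amap[v]) && !(y %in% amap) || (!is.na(amap[v]) && amap[v] == y)
        # both unmapped to the same target is impossible for a bond (x != y)
        if (ok_u && ok_v) {
          amap2 <- amap; amap2[u] <- x; amap2[v] <- y
          used_b2 <- used_b; used_b2[l] <- TRUE
          if (assign_next(k + 1, amap2, used_b2)) return(TRUE)
        }
      }
    }
    FALSE
  }
  assign_next(1, rep(NA_integer_, a$n_heavy_atoms), rep(FALSE, b$n_bonds))
}

oracle_mcs_bonds <- function(a, b) {
  if (a$n_bonds > b$n_bonds) { tmp <- a; a <- b; b <- tmp }
  for (s in rev(seq_len(a$n_bonds))) {
    subsets <- combn(a$n_bonds, s)
    for (ci in seq_len(ncol(subsets))) {
      sub <- subsets[, ci]
      if (!subset_connected(a$bonds$a1, a$bonds$a2, sub)) next
      if (embeds_into(a, sub, b)) return(s)
    }
  }
  0L
}

# --- independent BEDROC oracle: direct-sum min/max scaling --------------
oracle_bedroc <- function(ranks, n, N, alpha) {
  s <- sum(exp(-alpha * ranks / N))
  s_max <- sum(exp(-alpha * (1:n) / N))
  s_min <- sum(exp(-alpha * ((N - n + 1):N) / N))
  (s - s_min) / (s_max - s_min)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(rng) {
  q <- qr.Q(qr(matrix(rng_norm(rng, 9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

ob_canonical <- csmol:::ob_canonical
ob_smarts_count <- csmol:::ob_smarts_count
rng_norm <- csmol:::rng_norm
rng_unif <- csmol:::rng_unif
rng_sample <- csmol:::rng_sample
new_rng <- csmol:::new_rng
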