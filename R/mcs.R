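# Maximum-common-substructure similarity.
#
# similarity = N_bonds(MCS) / min(N_bonds(A), N_bonds(B))
#
# The MCS here is the maximum common *connected* edge subgraph. By default
# atoms are matched as wildcards (element-agnostic) and bonds are matched
# by ring-membership only, ignoring bond order; both policies are
# configurable. The search is an exact branch-and-bound up to a node
# budget; on exhaustion the best substructure found so far is returned and
# flagged.

bond_adjacency <- function(a1, a2) {
  m <- length(a1)
  lapply(seq_len(m), function(k) {
    which((a1 == a1[k] | a1 == a2[k] | a2 == a1[k] | a2 == a2[k]) &
            seq_len(m) != k)
  })
}

#' MCS similarity between two molecules
#'
#' @param a,b `csmol_molecule` objects with at least one bond each
#' @param match_elements if `TRUE`, atoms must agree on element; default
#'   `FALSE` (element-agnostic wildcard matching)
#' @param match_bond_order if `TRUE`, bonds must agree on (order, aromatic);
#'   default `FALSE` (ring-membership must agree in either case)
#' @param budget maximum number of search states before falling back to the
#'   best substructure found (`exact = FALSE` in the result)
#' @return list with `n_bonds_mcs`, `similarity`, `exact`
#' @examples
#' a <- parse_molecule("CC", "ethane"); b <- parse_molecule("CCC", "propane")
#' mcs_similarity(a, b)$similarity  # 1.0
#' @export
mcs_similarity <- function(a, b, match_elements = FALSE,
                           match_bond_order = FALSE, budget = 2e5) {
  stopifnot(inherits(a, "csmol_molecule"), inherits(b, "csmol_molecule"))
  if (a$n_bonds < 1 || b$n_bonds < 1) {
    stop("MCS similarity undefined for a molecule with 0 bonds", call. = FALSE)
  }
  # search maps bonds of the smaller molecule into the larger one
  if (a$n_bonds <= b$n_bonds) { A <- a; B <- b } else { A <- b; B <- a }
  nA <- A$n_heavy_atoms; nB <- B$n_heavy_atoms
  mA <- A$n_bonds; mB <- B$n_bonds
  Aa1 <- A$bonds$a1; Aa2 <- A$bonds$a2
  Ba1 <- B$bonds$a1; Ba2 <- B$bonds$a2

  atom_ok <- function(i, j) {
    !match_elements || A$atoms$element[i] == B$atoms$element[j]
  }
  bond_ok_vec <- outer(seq_len(mA), seq_len(mB), function(k, l) {
    ok <- A$bonds$in_ring[k] == B$bonds$in_ring[l]
    if (match_bond_order) {
      ok <- ok & A$bonds$order[k] == B$bonds$order[l] &
        A$bonds$aromatic[k] == B$bonds$aromatic[l]
    }
    ok
  })
  adjA <- bond_adjacency(Aa1, Aa2)

  env <- new.env(parent = emptyenv())
  env$best <- 0L
  env$nodes <- 0L
  env$exact <- TRUE

  # try to map A-bond k onto B-bond l with A-atoms (u,v) -> B-atoms (x,y)
  try_pair <- function(k, l, u, v, x, y, map, rmap, mappedA, usedB) {
    if (!is.na(map[u]) && map[u] != x) return(NULL)
    if (!is.na(map[v]) && map[v] != y) return(NULL)
    if (is.na(map[u]) && !is.na(rmap[x])) return(NULL)
    if (is.na(map[v]) && !is.na(rmap[y])) return(NULL)
    if (is.na(map[u]) && !atom_ok(u, x)) return(NULL)
    if (is.na(map[v]) && !atom_ok(v, y)) return(NULL)
    map[u] <- x; map[v] <- y; rmap[x] <- u; rmap[y] <- v
    mappedA[k] <- TRUE; usedB[l] <- TRUE
    list(map = map, rmap = rmap, mappedA = mappedA, usedB = usedB)
  }

  recurse <- function(map, rmap, mappedA, usedB, forbidden) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > budget) { env$exact <- FALSE; return(invisible()) }
    size <- sum(mappedA)
    if (size > env$best) env$best <- size
    # bound: every non-forbidden unmapped bond could in principle be added
    if (size + sum(!mappedA & !forbidden) <= env$best) return(invisible())
    # frontier: unmapped, unforbidden A-bonds adjacent to the mapped set
    cand <- which(!mappedA & !forbidden &
                    vapply(seq_len(mA), function(k) any(mappedA[adjA[[k]]]),
                           logical(1)))
    if (length(cand) == 0) return(invisible())
    k <- cand[1]
    u <- Aa1[k]; v <- Aa2[k]
    for (l in which(!usedB & bond_ok_vec[k, ])) {
      for (ori in 1:2) {
        x <- if (ori == 1) Ba1[l] else Ba2[l]
        y <- if (ori == 1) Ba2[l] else Ba1[l]
        st <- try_pair(k, l, u, v, x, y, map, rmap, mappedA, usedB)
        if (!is.null(st)) {
          recurse(st$map, st$rmap, st$mappedA, st$usedB, forbidden)
        }
      }
    }
    # branch: exclude bond k from the subgraph
    forbidden[k] <- TRUE
    recurse(map, rmap, mappedA, usedB, forbidden)
    invisible()
  }

  # root the subgraph at its minimum A-bond index to avoid duplicate work
  for (k0 in seq_len(mA)) {
    if (mA - k0 + 1 <= env$best) break
    forbidden <- seq_len(mA) < k0
    u <- Aa1[k0]; v <- Aa2[k0]
    for (l in which(bond_ok_vec[k0, ])) {
      for (ori in 1:2) {
        x <- if (ori == 1) Ba1[l] else Ba2[l]
        y <- if (ori == 1) Ba2[l] else Ba1[l]
        map <- rep(NA_integer_, nA); rmap <- rep(NA_integer_, nB)
        st <- try_pair(k0, l, u, v, x, y, map, rmap,
                       rep(FALSE, mA), rep(FALSE, mB))
        if (!is.null(st)) {
          recurse(st$map, st$rmap, st$mappedA, st$usedB, forbidden)
        }
      }
    }
  }

  list(
    n_bonds_mcs = as.integer(env$best),
    similarity = env$best / min(a$n_bonds, b$n_bonds),
    exact = env$exact
  )
}
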