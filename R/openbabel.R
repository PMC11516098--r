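#' @importFrom stats cor cov quantile rnorm runif sd setNames mahalanobis
#'   median
#' @importFrom utils read.csv write.csv combn
NULL

# Thin wrappers around ChemmineOB and the OpenBabel command-line tools.
# All format conversion, canonicalization and SMARTS matching goes through
# these; nothing else in the package talks to OpenBabel directly.

#' Canonicalize a SMILES string with OpenBabel
#'
#' @param smiles a single SMILES string
#' @return the canonical SMILES (no name field, trimmed)
#' @keywords internal
ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", out))
  out <- sub("\n.*$", "", out)
  trimws(out)
}

# SMILES -> V2000 MOL block (heavy atoms only, 2D coordinates)
ob_smiles_to_molblock <- function(smiles) {
  ChemmineOB::convertFormat("SMI", "SDF", source = smiles)
}

# MOL/SDF text -> SMILES in *input atom order* (non-canonical); used by
# randomize_smiles, which permutes the atom block first.
ob_molblock_to_smiles <- function(molblock) {
  out <- ChemmineOB::convertFormat("SDF", "SMI", source = molblock)
  trimws(sub("\t.*$", "", sub("\n.*$", "", out)))
}

# Count matches of a SMARTS pattern in one molecule given as a MOL block.
ob_smarts_count <- function(molblock, smarts) {
  n <- ChemmineOB::forEachMol("SDF", molblock, function(m) {
    ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE)
  })
  as.integer(n[[1]])
}

# OpenBabel binary fingerprints (FP2/FP3/FP4/MACCS) as 0/1 integer vectors.
ob_fingerprint <- function(molblock, name = "FP2") {
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SDF", molblock, function(m) m), name
  )
  if (is.matrix(fp)) fp <- fp[1, ]
  as.integer(fp)
}
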