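# Conformer ensemble generation, strain filtering and RMSD clustering.
#
# Two schemes mirror the two conformational-search regimes: a broad
# "global" ensemble (strain threshold 1.4806 kcal/mol per rotatable bond,
# 1 A clustering) and a tight "near_native" ensemble (0.5060 kcal/mol per
# rotatable bond, 2 A clustering). Strain = conformer energy minus the
# ensemble minimum. The built-in generation backend is seeded
# distance-geometry embedding (ETKDG, via a bundled helper script)
# followed by MMFF94 minimization; deterministic for a fixed seed. Any
# backend returning (coordinates, energy) per conformer can be plugged in.

#' Conformational-search scheme parameters
#'
#' @param name `"global"` or `"near_native"`
#' @param max_conformers search budget for the backend
#' @return list with `name`, `strain_factor_kcal_per_rotbond`,
#'   `rmsd_cutoff_angstrom`, `max_conformers`
#' @export
ensemble_scheme <- function(name = c("global", "near_native"),
                            max_conformers = 200) {
  name <- match.arg(name)
  if (name == "global") {
    list(name = "global", strain_factor_kcal_per_rotbond = 1.4806,
         rmsd_cutoff_angstrom = 1.0, max_conformers = max_conformers)
  } else {
    list(name = "near_native", strain_factor_kcal_per_rotbond = 0.5060,
         rmsd_cutoff_angstrom = 2.0, max_conformers = max_conformers)
  }
}

parse_sdf_records <- function(sdf_text) {
  recs <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[vapply(recs, function(r) grepl("V2000", r), logical(1))]
  lapply(recs, function(r) {
    lines <- strsplit(r, "\n", fixed = TRUE)[[1]]
    while (length(lines) > 0 && !nzchar(trimws(lines[1])) &&
           !grepl("V2000", lines[min(4, length(lines))])) lines <- lines[-1]
    n_atoms <- as.integer(substr(lines[4], 1, 3))
    atom_lines <- lines[5:(4 + n_atoms)]
    list(
      element = trimws(substr(atom_lines, 32, 34)),
      xyz = cbind(as.numeric(substr(atom_lines, 1, 10)),
                  as.numeric(substr(atom_lines, 11, 20)),
                  as.numeric(substr(atom_lines, 21, 30))),
      lines = lines
    )
  })
}

#' Generate an unfiltered conformer ensemble
#'
#' @param mol a `csmol_molecule`
#' @param budget maximum conformers requested from the backend
#' @param seed integer; the API requires an explicit seed even though the
#'   built-in systematic backend is deterministic by construction
#' @param backend a function `(mol, budget, seed) -> list(conformers,
#'   elements)`; defaults to the distance-geometry + MMFF94 backend
#' @return a `csmol_ensemble`: `molecule_id`, `scheme` (`NA` until
#'   filtered), `elements`, `conformers` (list of `list(xyz, energy)`),
#'   `strain_energies`, `n_rotatable_bonds`
#' @export
generate_conformers <- function(mol, budget = 200, seed = 1,
                                backend = distgeom_backend) {
  stopifnot(inherits(mol, "csmol_molecule"), budget >= 1)
  raw <- backend(mol, budget, seed)
  energies <- vapply(raw$conformers, `[[`, numeric(1), "energy")
  structure(list(
    molecule_id = mol$id,
    scheme = NA_character_,
    elements = raw$elements,
    conformers = raw$conformers,
    strain_energies = energies - min(energies),
    n_rotatable_bonds = mol$n_rotatable_bonds
  ), class = "csmol_ensemble")
}

find_python <- function() {
  py <- getOption("csmol.python", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the conformer backend",
                        call. = FALSE)
  py
}

# Batch driver for the built-in backend: one helper-script invocation for
# many molecules. Returns a named list (by molecule id) of
# list(elements, conformers).
run_distgeom_batch <- function(smiles, ids, budget, seed) {
  script <- system.file("python", "gen_conformers.py", package = "csmol")
  if (!nzchar(script)) {  # running from a source checkout
    script <- file.path("inst", "python", "gen_conformers.py")
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, ids), fin)
  log <- suppressWarnings(system2(
    find_python(), c(script, fin, fout, as.character(budget), as.character(seed)),
    stdout = TRUE, stderr = TRUE))
  fails <- grep("^#FAIL", log, value = TRUE)
  if (length(fails) > 0) {
    stop("conformer generation failed: ", paste(fails, collapse = "; "),
         call. = FALSE)
  }
  if (!file.exists(fout) || file.size(fout) == 0) {
    stop("conformer backend produced no output: ", paste(log, collapse = " "),
         call. = FALSE)
  }
  recs <- parse_sdf_records(paste(readLines(fout), collapse = "\n"))
  field <- function(lines, tag) {
    i <- grep(paste0("<", tag, ">"), lines, fixed = TRUE)
    if (length(i) == 0) NA_character_ else lines[i[1] + 1]
  }
  rec_ids <- vapply(recs, function(r) field(r$lines, "mol_id"), character(1))
  out <- list()
  for (id in unique(rec_ids)) {
    sel <- recs[rec_ids == id]
    out[[id]] <- list(
      elements = sel[[1]]$element,
      conformers = lapply(sel, function(r) list(
        xyz = r$xyz,
        energy = as.numeric(field(r$lines, "energy_kcal"))
      ))
    )
  }
  out
}

# Built-in backend (single molecule): seeded ETKDG distance-geometry
# embedding + MMFF94 minimization.
distgeom_backend <- function(mol, budget, seed) {
  run_distgeom_batch(mol$smiles, mol$id, budget, seed)[[mol$id]]
}

#' Heavy-atom RMSD after optimal (Kabsch) superposition
#'
#' @param xyz1,xyz2 coordinate matrices (same atom order)
#' @param heavy logical mask of heavy atoms (default: all rows)
#' @return RMSD in Angstrom
#' @export
conformer_rmsd <- function(xyz1, xyz2, heavy = rep(TRUE, nrow(xyz1))) {
  p <- xyz1[heavy, , drop = FALSE]
  q <- xyz2[heavy, , drop = FALSE]
  p <- sweep(p, 2, colMeans(p)); q <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(q, p))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((p - q %*% rot)^2)))
}

#' Strain-filter a conformer ensemble
#'
#' Keeps conformers whose strain energy does not exceed
#' `strain_factor * max(n_rotatable_bonds, 1)`; the global minimum is
#' always retained (its strain is 0).
#'
#' @param ens a `csmol_ensemble`
#' @param scheme an [ensemble_scheme()]
#' @return the filtered `csmol_ensemble`, tagged with the scheme name
#' @export
strain_filter <- function(ens, scheme) {
  stopifnot(inherits(ens, "csmol_ensemble"))
  if (length(ens$conformers) == 0) stop("empty ensemble", call. = FALSE)
  thr <- scheme$strain_factor_kcal_per_rotbond * max(ens$n_rotatable_bonds, 1)
  keep <- ens$strain_energies <= thr
  keep[which.min(ens$strain_energies)] <- TRUE
  ens$conformers <- ens$conformers[keep]
  ens$strain_energies <- ens$strain_energies[keep]
  ens$scheme <- scheme$name
  ens
}

#' Cluster a strain-filtered ensemble by RMSD (energy-ascending leader)
#'
#' Conformers are visited in order of increasing energy; each becomes a
#' cluster representative unless it lies within `rmsd_cutoff` of an
#' existing representative. Representatives are therefore the
#' lowest-energy members of their clusters and are pairwise separated by
#' more than the cutoff.
#'
#' @inheritParams strain_filter
#' @return the clustered `csmol_ensemble`
#' @export
rmsd_cluster <- function(ens, scheme) {
  stopifnot(inherits(ens, "csmol_ensemble"))
  n <- length(ens$conformers)
  if (n <= 1) { ens$scheme <- scheme$name; return(ens) }
  heavy <- ens$elements != "H"
  ord <- order(ens$strain_energies)
  reps <- integer(0)
  for (i in ord) {
    is_new <- TRUE
    for (r in reps) {
      if (conformer_rmsd(ens$conformers[[i]]$xyz, ens$conformers[[r]]$xyz,
                         heavy) <= scheme$rmsd_cutoff_angstrom) {
        is_new <- FALSE; break
      }
    }
    if (is_new) reps <- c(reps, i)
  }
  reps <- sort(reps)
  ens$conformers <- ens$conformers[reps]
  ens$strain_energies <- ens$strain_energies[reps]
  ens$scheme <- scheme$name
  ens
}

#' Build a filtered, clustered ensemble for one molecule
#'
#' Convenience composition: generate, strain-filter, RMSD-cluster.
#'
#' @inheritParams generate_conformers
#' @param scheme an [ensemble_scheme()]
#' @export
build_ensemble <- function(mol, scheme, budget = scheme$max_conformers,
                           seed = 1, backend = distgeom_backend) {
  ens <- generate_conformers(mol, budget = budget, seed = seed,
                             backend = backend)
  rmsd_cluster(strain_filter(ens, scheme), scheme)
}

#' Write a conformer ensemble to SDF
#'
#' One record per conformer with `<mol_id>` and `<strain_kcal>` data fields.
#'
#' @param ens a `csmol_ensemble`
#' @param path output path
#' @export
write_ensemble_sdf <- function(ens, path) {
  out <- character(0)
  n <- length(ens$elements)
  for (i in seq_along(ens$conformers)) {
    xyz <- ens$conformers[[i]]$xyz
    rec <- c(
      paste0(ens$molecule_id, "_conf", i), " csmol", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], ens$elements),
      "M  END",
      ">  <mol_id>", ens$molecule_id, "",
      ">  <strain_kcal>", format(ens$strain_energies[i], digits = 8), "",
      "$$$$"
    )
    out <- c(out, rec)
  }
  writeLines(out, path)
}

#' Read a conformer ensemble from SDF written by [write_ensemble_sdf()]
#'
#' @param path SDF path
#' @return a `csmol_ensemble` (energies reconstructed from strain fields)
#' @export
read_ensemble_sdf <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  chunks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  chunks <- chunks[grepl("V2000", chunks)]
  get_field <- function(lines, tag) {
    i <- grep(paste0("^>\\s+<", tag, ">"), lines)
    if (length(i) == 0) NA_character_ else lines[i[1] + 1]
  }
  confs <- list(); strains <- numeric(0); mol_id <- NA_character_; elements <- NULL
  for (ch in chunks) {
    lines <- strsplit(ch, "\n", fixed = TRUE)[[1]]
    if (!nzchar(trimws(lines[1])) && length(lines) > 4) lines <- lines[-1]
    n_atoms <- as.integer(substr(lines[4], 1, 3))
    al <- lines[5:(4 + n_atoms)]
    xyz <- cbind(as.numeric(substr(al, 1, 10)), as.numeric(substr(al, 11, 20)),
                 as.numeric(substr(al, 21, 30)))
    elements <- trimws(substr(al, 32, 34))
    mol_id <- get_field(lines, "mol_id")
    strains <- c(strains, as.numeric(get_field(lines, "strain_kcal")))
    confs[[length(confs) + 1]] <- list(xyz = xyz, energy = NA_real_)
  }
  for (i in seq_along(confs)) confs[[i]]$energy <- strains[i]
  structure(list(
    molecule_id = mol_id, scheme = NA_character_, elements = elements,
    conformers = confs, strain_energies = strains,
    n_rotatable_bonds = NA_integer_
  ), class = "csmol_ensemble")
}
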