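# Conformer generation, strain filtering, RMSD clustering.

# synthetic backend for arithmetic tests: fixed coordinates + energies
stub_backend <- function(confs) {
  function(mol, budget, seed) {
    list(elements = rep("C", nrow(confs[[1]]$xyz)), conformers = confs)
  }
}

tri <- function(shift = 0, scale = 1) {
  matrix(c(0, 0, 0, 1.5, 0, 0, 0.75, 1.3, 0), 3, 3, byrow = TRUE) * scale +
    shift
}

test_that("scheme parameters carry the published constants", {
  g <- ensemble_scheme("global"); nn <- ensemble_scheme("near_native")
  expect_equal(g$strain_factor_kcal_per_rotbond, 1.4806)
  expect_equal(g$rmsd_cutoff_angstrom, 1.0)
  expect_equal(nn$strain_factor_kcal_per_rotbond, 0.5060)
  expect_equal(nn$rmsd_cutoff_angstrom, 2.0)
  expect_lt(nn$strain_factor_kcal_per_rotbond, g$strain_factor_kcal_per_rotbond)
})

test_that("strain_filter applies the rotatable-bond threshold", {
  confs <- lapply(c(0, 0.3, 1.0), function(e) list(xyz = tri(), energy = e))
  m <- mol("CCO")  # placeholder molecule; n_rot overridden below
  ens <- generate_conformers(m, budget = 3, seed = 1,
                             backend = stub_backend(confs))
  ens$n_rotatable_bonds <- 1L
  expect_equal(length(strain_filter(ens, ensemble_scheme("near_native"))$conformers), 2)
  expect_equal(length(strain_filter(ens, ensemble_scheme("global"))$conformers), 3)
  # rigid molecule: max(n_rot, 1) keeps the threshold positive
  confs2 <- lapply(c(0, 0.2), function(e) list(xyz = tri(), energy = e))
  ens2 <- generate_conformers(m, budget = 2, seed = 1,
                              backend = stub_backend(confs2))
  ens2$n_rotatable_bonds <- 0L
  expect_equal(length(strain_filter(ens2, ensemble_scheme("near_native"))$conformers), 2)
  # empty ensembles are an error
  ens3 <- ens; ens3$conformers <- list()
  expect_error(strain_filter(ens3, ensemble_scheme("global")), "empty")
})

test_that("leader clustering keeps lowest-energy representatives", {
  # construct conformers with RMSD(1,2) ~ 0.5, RMSD(1,3) = RMSD(2,3) ~ > 2
  c1 <- tri()
  c2 <- tri(); c2[3, 2] <- c2[3, 2] - 0.9        # ~0.5 A from c1
  c3 <- tri(scale = 3)                           # far from both
  confs <- list(list(xyz = c1, energy = 0), list(xyz = c2, energy = 0.1),
                list(xyz = c3, energy = 0.2))
  ens <- generate_conformers(mol("CCO"), budget = 3, seed = 1,
                             backend = stub_backend(confs))
  sch <- ensemble_scheme("global")  # cutoff 1.0
  out <- rmsd_cluster(ens, sch)
  expect_equal(out$strain_energies, c(0, 0.2))
  # single conformer maps to itself
  one <- ens; one$conformers <- ens$conformers[1]; one$strain_energies <- 0
  expect_equal(length(rmsd_cluster(one, sch)$conformers), 1)
  # all pairwise above the cutoff: everything retained
  far <- list(list(xyz = tri(), energy = 0), list(xyz = tri(scale = 3), energy = 1),
              list(xyz = tri(scale = 6), energy = 2))
  ensf <- generate_conformers(mol("CCO"), budget = 3, seed = 1,
                              backend = stub_backend(far))
  expect_equal(length(rmsd_cluster(ensf, sch)$conformers), 3)
  # representatives are pairwise separated by more than the cutoff
  reps <- rmsd_cluster(ensf, sch)
  for (i in seq_along(reps$conformers)) {
    for (j in seq_len(i - 1)) {
      expect_gt(conformer_rmsd(reps$conformers[[i]]$xyz,
                               reps$conformers[[j]]$xyz), sch$rmsd_cutoff_angstrom)
    }
  }
})

test_that("RMSD is invariant to rigid rotation and translation", {
  rng <- new_rng(5)
  m <- mol("CCCCO", "butanol")
  ens <- generate_conformers(m, budget = 20, seed = 2)
  xyz <- ens$conformers[[1]]$xyz
  for (i in 1:5) {
    rot <- random_rotation(rng)
    moved <- xyz %*% rot + matrix(rng_norm(rng, 3), nrow(xyz), 3, byrow = TRUE)
    expect_lt(conformer_rmsd(xyz, moved, ens$elements != "H"), 1e-6)
  }
})

test_that("the built-in backend is deterministic and covers torsional minima", {
  m <- mol("CCCCCC", "hexane")
  e1 <- generate_conformers(m, budget = 200, seed = 4)
  e2 <- generate_conformers(m, budget = 200, seed = 4)
  expect_identical(vapply(e1$conformers, `[[`, numeric(1), "energy"),
                   vapply(e2$conformers, `[[`, numeric(1), "energy"))
  # >= 3 distinct torsional minima before filtering
  expect_gte(length(unique(round(e1$strain_energies, 1))), 3)
  # rigid methane: one distinct conformer
  em <- generate_conformers(mol("C", "methane"), budget = 5, seed = 1)
  expect_equal(length(em$conformers), 1)
})

test_that("strain filtering is monotone in the factor, clustering in the cutoff", {
  m <- mol("CCCCCO", "pentanol")
  ens <- generate_conformers(m, budget = 100, seed = 3)
  kept <- vapply(c(0.2, 0.5060, 1.0, 1.4806, 3), function(f) {
    sch <- ensemble_scheme("global"); sch$strain_factor_kcal_per_rotbond <- f
    length(strain_filter(ens, sch)$conformers)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
  filt <- strain_filter(ens, ensemble_scheme("global"))
  reps <- vapply(c(0.25, 0.5, 1, 2, 4), function(cut) {
    sch <- ensemble_scheme("global"); sch$rmsd_cutoff_angstrom <- cut
    length(rmsd_cluster(filt, sch)$conformers)
  }, numeric(1))
  expect_true(all(diff(reps) <= 0))
})

test_that("ensembles round-trip through SDF with strain fields", {
  m <- mol("CCCCO", "butanol")
  ens <- build_ensemble(m, ensemble_scheme("global"), budget = 50, seed = 9)
  f <- tempfile(fileext = ".sdf")
  write_ensemble_sdf(ens, f)
  back <- read_ensemble_sdf(f)
  expect_equal(back$molecule_id, "butanol")
  expect_equal(length(back$conformers), length(ens$conformers))
  expect_equal(back$strain_energies, ens$strain_energies, tolerance = 1e-6)
  expect_equal(back$conformers[[1]]$xyz, ens$conformers[[1]]$xyz,
               tolerance = 1e-4, ignore_attr = TRUE)
})
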