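# Conformer-pair scoring and CSS descriptor reduction.

test_that("score_pair is 1 for identical conformers and directional otherwise", {
  ens <- generate_conformers(mol("c1ccccc1", "benzene"), budget = 5, seed = 1)
  cf <- list(xyz = ens$conformers[[1]]$xyz, heavy = ens$elements != "H",
             features = "aromatic")
  expect_equal(score_pair(cf, cf), 1.0)

  # benzene query vs phenol reference: coverage 1/3; reversed: 1
  ensp <- generate_conformers(mol("c1ccccc1O", "phenol"), budget = 5, seed = 1)
  cfp <- list(xyz = ensp$conformers[[1]]$xyz, heavy = ensp$elements != "H",
              features = c("donor", "acceptor", "aromatic"))
  s_b_to_p <- score_pair(cf, cfp)  # query benzene onto reference phenol
  s_p_to_b <- score_pair(cfp, cf)
  expect_gt(s_p_to_b, s_b_to_p)
  shape <- 1 / (1 + mean(abs(usr_moments(cf$xyz, cf$heavy) -
                               usr_moments(cfp$xyz, cfp$heavy))))
  expect_equal(s_b_to_p, shape * (1 / 3))
  expect_equal(s_p_to_b, shape * 1)
  expect_true(s_b_to_p >= 0 && s_b_to_p <= 1)
  # degenerate geometry
  expect_error(score_pair(list(xyz = matrix(0, 2, 3), heavy = c(TRUE, TRUE),
                               features = character(0)), cf), "degenerate")
})

test_that("score_ensembles builds the full matrix and checks schemes", {
  g <- ensemble_scheme("global")
  m1 <- mol("CCCCO", "butanol"); m2 <- mol("CCCC", "butane")
  e1 <- attach_features(build_ensemble(m1, g, budget = 30, seed = 1), m1)
  e2 <- attach_features(build_ensemble(m2, g, budget = 30, seed = 1), m2)
  mat <- score_ensembles(e1, e2)
  expect_equal(dim(mat$scores),
               c(length(e1$conformers), length(e2$conformers)))
  expect_true(all(mat$scores >= 0 & mat$scores <= 1))
  # identical ensembles: diagonal entries are exactly 1
  self <- score_ensembles(e1, e1)
  expect_equal(unname(diag(self$scores)), rep(1, length(e1$conformers)))
  # scheme mismatch is an error
  e2n <- e2; e2n$scheme <- "near_native"
  expect_error(score_ensembles(e1, e2n), "scheme mismatch")
})

test_that("reduce_raw takes matrix extrema per scheme", {
  pm <- function(v) structure(list(query_id = "a", reference_id = "b",
                                   scheme = "global",
                                   scores = matrix(v, nrow = 1)),
                              class = "csmol_pair_matrix")
  raw <- reduce_raw(pm(c(0.8, 0.2, 0.5)), pm(c(0.7, 0.3)))
  expect_equal(raw, list(Global_MAX = 0.8, Global_MIN = 0.2,
                         Near_MAX = 0.7, Near_MIN = 0.3))
  ones <- reduce_raw(pm(rep(1, 4)), pm(rep(1, 2)))
  expect_true(all(unlist(ones) == 1))
  single <- reduce_raw(pm(0.4), pm(0.4))
  expect_equal(single$Global_MAX, single$Global_MIN)
  empty <- pm(0.4); empty$scores <- matrix(numeric(0), 0, 0)
  expect_error(reduce_raw(empty, pm(0.4)), "empty")
})

test_that("advanced descriptors follow the stated arithmetic", {
  raw_ab <- list(Global_MAX = 0.8, Global_MIN = 0.2, Near_MAX = 0.7,
                 Near_MIN = 0.3)
  raw_ba <- list(Global_MAX = 0.6, Global_MIN = 0.4, Near_MAX = 0.5,
                 Near_MIN = 0.45)
  adv <- advanced_descriptors(raw_ab, raw_ba)
  expect_equal(adv$MaxSim, 0.8)
  expect_equal(adv$MaxDistance, 0.2)
  expect_equal(adv$MaxOverlap, 0.5)
  expect_equal(adv$MaxAggregation, 0.75)
  expect_equal(adv$CrossSim, (0.8 + 0.6) / 2)
  # all-ones raw gives all-ones advanced
  ones <- advanced_descriptors(
    list(Global_MAX = 1, Global_MIN = 1, Near_MAX = 1, Near_MIN = 1),
    list(Global_MAX = 1, Global_MIN = 1, Near_MAX = 1, Near_MIN = 1))
  expect_true(all(unlist(ones) == 1))
  # Cross averages the two directions
  expect_equal(advanced_descriptors(raw_ab, raw_ba)$CrossOverlap,
               (adv$MaxOverlap + (0.6 + 0.4) / 2) / 2)
})

test_that("label_pairs is deterministic, self-consistent and swap-stable", {
  mols <- list(mol("c1ccccc1", "benzene"), mol("c1ccccc1O", "phenol"),
               mol("CCCCO", "butanol"))
  names(mols) <- vapply(mols, `[[`, character(1), "id")
  pairs <- data.frame(id_a = c("benzene", "phenol", "butanol"),
                      id_b = c("phenol", "benzene", "butanol"))
  lab1 <- label_pairs(mols, pairs, budget = 30, seed = 5)
  lab2 <- label_pairs(mols, pairs, budget = 30, seed = 5)
  expect_identical(lab1, lab2)
  # self-pair: MaxSim and MCS exactly 1
  expect_equal(lab1$MaxSim[3], 1, tolerance = 1e-6)
  expect_equal(lab1$MCS[3], 1)
  # swapped pair: identical Cross*, exchanged directional values
  for (col in c("CrossSim", "CrossDistance", "CrossOverlap",
                "CrossAggregation")) {
    expect_equal(lab1[[col]][1], lab1[[col]][2])
  }
  expect_equal(lab1$Global_MAX_ab[1], lab1$Global_MAX_ba[2])
  # algebra invariants on every row
  expect_true(all(abs(lab1$MaxOverlap -
                        (lab1$MaxSim + lab1$MaxDistance) / 2) < 1e-12))
  expect_true(all(lab1$MaxDistance <= lab1$MaxSim))
  # unknown ids are reported
  expect_error(label_pairs(mols, data.frame(id_a = "x", id_b = "benzene")),
               "not in library")
})

test_that("descriptors are invariant to rigid rotation of one molecule", {
  g <- ensemble_scheme("global"); nn <- ensemble_scheme("near_native")
  m1 <- mol("CCCCO", "butanol"); m2 <- mol("CCOC", "ether")
  ens <- generate_conformers(m1, budget = 30, seed = 1)
  e1g <- attach_features(rmsd_cluster(strain_filter(ens, g), g), m1)
  e1n <- attach_features(rmsd_cluster(strain_filter(ens, nn), nn), m1)
  ens2 <- generate_conformers(m2, budget = 30, seed = 1)
  e2g <- attach_features(rmsd_cluster(strain_filter(ens2, g), g), m2)
  e2n <- attach_features(rmsd_cluster(strain_filter(ens2, nn), nn), m2)
  raw0 <- reduce_raw(score_ensembles(e1g, e2g), score_ensembles(e1n, e2n))
  rng <- new_rng(11); rot <- random_rotation(rng)
  rot_ens <- function(e) {
    e$conformers <- lapply(e$conformers, function(cf) {
      cf$xyz <- cf$xyz %*% rot + 2.5; cf })
    e
  }
  raw1 <- reduce_raw(score_ensembles(rot_ens(e1g), e2g),
                     score_ensembles(rot_ens(e1n), e2n))
  expect_equal(unlist(raw0), unlist(raw1), tolerance = 1e-6)
})

test_that("scheme nesting orders the raw descriptors", {
  # near-native ensemble is a subset of the global one, so Near_MAX <=
  # Global_MAX and Near_MIN >= Global_MIN per direction
  mols <- list(mol("CCCCCO", "pentanol"), mol("CCCCC", "pentane"))
  names(mols) <- c("pentanol", "pentane")
  lab <- label_pairs(mols, data.frame(id_a = "pentanol", id_b = "pentane"),
                     budget = 80, seed = 2)
  expect_lte(lab$Near_MAX_ab, lab$Global_MAX_ab)
  expect_gte(lab$Near_MIN_ab, lab$Global_MIN_ab)
  expect_lte(lab$Near_MAX_ba, lab$Global_MAX_ba)
  expect_gte(lab$Near_MIN_ba, lab$Global_MIN_ba)
})

test_that("label tables round-trip through the fixed CSV layout", {
  mols <- list(mol("c1ccccc1", "benzene"), mol("c1ccccc1O", "phenol"))
  names(mols) <- c("benzene", "phenol")
  lab <- label_pairs(mols, data.frame(id_a = "benzene", id_b = "phenol"),
                     budget = 10, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_label_csv(lab, f)
  back <- read_label_csv(f)
  expect_true(all(csmol:::CSS_COLUMNS %in% names(back)))
  expect_equal(back$MaxSim, lab$MaxSim, tolerance = 1e-12)
})
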