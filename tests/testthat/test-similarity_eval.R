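# Encoding similarity, ranking metrics, screening, target identification,
# benchmark curation, fingerprint baselines.

test_that("cosine and pearson similarities match direct computation", {
  v <- c(1, 2, 3)
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / sqrt(14 * 77))  # 0.974631...
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "mismatch")

  expect_equal(pearson_similarity(v, 2 * v + 3), 1.0)
  expect_equal(pearson_similarity(v, -v), -1.0)
  expect_equal(pearson_similarity(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_similarity(c(1, 1, 1), v), "constant")
  # affine invariance at tight tolerance
  rng <- new_rng(1)
  x <- rng_norm(rng, 50)
  expect_equal(pearson_similarity(x, 3.7 * x + 2), 1, tolerance = 1e-12)
  expect_equal(pearson_similarity(x, -0.2 * x + 5), -1, tolerance = 1e-12)
})

test_that("bedroc hits its endpoints and matches the direct-sum oracle", {
  expect_equal(bedroc(1:10, 10, 1000, 160.9), 1.0, tolerance = 1e-9)
  expect_equal(bedroc(991:1000, 10, 1000, 160.9), 0.0, tolerance = 1e-9)
  expect_error(bedroc(1:10, 10, 1000, alpha = -1), "positive")
  rng <- new_rng(31)
  for (i in 1:1000) {
    N <- 50 + floor(rng_unif(rng, 1, 0, 950))
    n <- 1 + floor(rng_unif(rng, 1, 0, min(20, N - 1)))
    alpha <- rng_unif(rng, 1, 1, 200)
    ranks <- rng_sample(rng, N, size = n)
    expect_equal(bedroc(ranks, n, N, alpha),
                 oracle_bedroc(ranks, n, N, alpha), tolerance = 1e-9)
  }
})

test_that("random rankings average to the closed-form bedroc expectation", {
  rng <- new_rng(8)
  N <- 1000; n <- 10; alpha <- 160.9
  vals <- vapply(1:10000, function(i) {
    bedroc(rng_sample(rng, N, size = n), n, N, alpha)
  }, numeric(1))
  expected <- csmol:::bedroc_random_mean(n, N, alpha)
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * mc_se)
})

test_that("enrichment factor arithmetic", {
  expect_equal(enrichment_factor(1:10, 10, 1000, 0.01), 100.0)
  expect_equal(enrichment_factor(c(5, 501:509), 10, 1000, 0.01), 10.0)
  rng <- new_rng(9)
  vals <- vapply(1:4000, function(i) {
    enrichment_factor(rng_sample(rng, 1000, size = 10), 10, 1000, 0.01)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("auroc equals the Mann-Whitney statistic", {
  rng <- new_rng(12)
  for (i in 1:20) {
    scores <- rng_norm(rng, 60)
    lab <- rng_unif(rng, 60) < 0.3
    if (!any(lab) || all(lab)) next
    w <- wilcox.test(scores[lab], scores[!lab], exact = FALSE)
    expect_equal(auroc(scores, lab),
                 unname(w$statistic) / (sum(lab) * sum(!lab)))
  }
  expect_error(auroc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("screen uses max-over-references and stable tie ranking", {
  enc <- diag(4); rownames(enc) <- c("a", "b", "c", "d")
  ref <- rbind(enc["a", ], enc["a", ] * 0.5 + 1e-3)  # 2nd ref never wins
  active <- c(TRUE, FALSE, FALSE, FALSE)
  r1 <- screen(ref, enc, active)
  r2 <- screen(enc["a", , drop = FALSE], enc, active)
  expect_equal(r1$scores$score[1], 1)  # active duplicates the reference
  expect_equal(r1$bedroc, r2$bedroc)
  expect_equal(r1$auroc, 1)
  # library row order does not change the metrics (stable ties by id)
  perm <- c(3, 1, 4, 2)
  r3 <- screen(ref, enc[perm, ], active[perm])
  expect_equal(r3$bedroc, r1$bedroc)
  expect_equal(r3$scores$rank[match(rownames(enc), r3$scores$id)],
               r1$scores$rank)
  # head-name metric without a model errors
  expect_error(screen(ref, enc, active,
                      screening_config(metric = "MaxSim")), "checkpoint")
})

test_that("target_id scores targets by their best ligand", {
  rng <- new_rng(14)
  D <- 8
  lib <- matrix(rng_norm(rng, 50 * D), 50, D)
  rownames(lib) <- sprintf("L%02d", 1:50)
  targets <- lapply(1:50, function(i) sprintf("T%02d", ((i - 1) %% 25) + 1))
  # query identical to ligand 3 -> its target scores 1 under cosine
  res <- target_id(lib[3, ], lib, targets, true_targets = targets[[3]])
  expect_equal(max(res$target_scores$score), 1)
  expect_equal(res$target_scores$score[res$target_scores$target ==
                                         targets[[3]]], 1)
  # all-equal similarities give AUROC 0.5
  same <- matrix(1, 10, D); rownames(same) <- sprintf("S%02d", 1:10)
  tg <- lapply(1:10, function(i) sprintf("T%02d", i))
  res2 <- target_id(rep(1, D), same, tg, true_targets = c("T01", "T02"))
  expect_equal(res2$auroc, 0.5)
  # true-target ligands duplicated from the query -> AUROC 1
  q <- rng_norm(rng, D)
  lib3 <- rbind(lib, q, q)
  rownames(lib3) <- c(rownames(lib), "X1", "X2")
  tg3 <- c(targets, list("TA"), list("TB"))
  res3 <- target_id(q, lib3, tg3, true_targets = c("TA", "TB"))
  expect_equal(res3$auroc, 1)
  expect_error(target_id(lib[1, ], lib, targets, true_targets = "NOPE"),
               "no annotated target")
  # reduces to screen() when every target has exactly one ligand
  one_per <- lapply(1:50, function(i) sprintf("U%02d", i))
  resu <- target_id(lib[3, ], lib, one_per, true_targets = "U03")
  scr <- screen(lib[3, , drop = FALSE], lib,
                active = seq_len(50) == 3)
  expect_equal(resu$auroc, scr$auroc)
  expect_equal(resu$bedroc, scr$bedroc)
})

test_that("benchmark curation applies the four filter stages in order", {
  tbl <- data.frame(
    ligand_id = c("q1", "q1", "q2", "q3", "d1", "d2"),
    smiles = c("CC(=O)Nc1ccc(O)cc1", "CC(=O)Nc1ccc(O)cc1",
               "c1ccccc1", "CCCCCCCCCCCCCC",
               "Clc1ccc(Cl)cc1", "O=C(O)c1ccccc1"),
    target = c("T1", "T2", "T1", "T3", "T2", "T3"),
    affinity_value = c(5, 20000, 10, 8, 3, 2),
    affinity_unit = c("nM", "nM", "nM", "nM", "nM", "nM"),
    n_entries = c(301, 301, 299, 400, 50, 50),
    stringsAsFactors = FALSE
  )
  # q1: 301 entries, 11 heavy atoms -> passes entries, passes heavy (11 >= 12? no)
  # paracetamol has 11 heavy atoms -> q1 dropped at stage 1;
  # q3 (14 heavy atoms, 400 entries) is the only stage-1 query
  res <- build_target_benchmark(tbl, min_targets = 1)
  expect_equal(res$manifest$stage1_queries, 1)
  expect_true("q3" %in% names(res$queries))
  # 20 uM link dropped at stage 2
  tbl2 <- tbl; tbl2$n_entries[1:2] <- 400
  tbl2$smiles[tbl2$ligand_id == "q1"] <- "CC(=O)Nc1ccc(OC)cc1"  # 12 heavy
  res2 <- build_target_benchmark(tbl2, min_targets = 0)
  expect_false("T2" %in% res2$queries$q1$true_targets)
  # identical library ligand (MCS 1) dropped at stage 3
  tbl3 <- rbind(tbl2, data.frame(
    ligand_id = "twin", smiles = "CC(=O)Nc1ccc(OC)cc1", target = "T9",
    affinity_value = 1, affinity_unit = "nM", n_entries = 10))
  res3 <- build_target_benchmark(tbl3, min_targets = 0)
  expect_false("twin" %in% res3$queries$q1$library)
  # unit errors
  tblu <- tbl; tblu$affinity_unit[1] <- "banana"
  expect_error(build_target_benchmark(tblu), "unconvertible")
  # micromolar conversion: 20 uM > 10 uM threshold
  tblm <- tbl2; tblm$affinity_value[2] <- 20; tblm$affinity_unit[2] <- "uM"
  res4 <- build_target_benchmark(tblm, min_targets = 0)
  expect_false("T2" %in% res4$queries$q1$true_targets)
})

test_that("fingerprint baselines cover the metric family", {
  a <- mol("CC(=O)Nc1ccc(O)cc1", "paracetamol")
  b <- mol("CC(=O)Nc1ccc(OC)cc1", "methylated")
  for (fp in c("path", "FP2", "MACCS")) {
    expect_equal(fingerprint_baseline(a, a, fp, "Tanimoto"), 1.0, info = fp)
  }
  # Tversky is asymmetric in alpha and bounded below by Tanimoto
  # (alpha*a + (1-alpha)*b <= a + b for alpha in [0, 1])
  t01 <- fingerprint_baseline(a, b, "path", "Tversky", alpha = 0.01)
  t99 <- fingerprint_baseline(a, b, "path", "Tversky", alpha = 0.99)
  tan <- fingerprint_baseline(a, b, "path", "Tanimoto")
  expect_false(isTRUE(all.equal(t01, t99)))
  expect_gte(t01, tan)
  expect_gte(t99, tan)
  # alpha = 0.5 halves the private features: equals Dice
  expect_equal(fingerprint_baseline(a, b, "path", "Tversky", alpha = 0.5),
               fingerprint_baseline(a, b, "path", "Dice"))
  # all metrics stay in [0, 1]
  for (metric in csmol:::FP_METRICS) {
    v <- fingerprint_baseline(a, b, "path", metric)
    expect_true(v >= 0 && v <= 1, info = metric)
  }
  expect_error(fingerprint_baseline(a, b, "path", "NotAMetric"), "unknown")
  expect_error(fingerprint_baseline(a, b, "NotAFp"), "unknown")
})
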