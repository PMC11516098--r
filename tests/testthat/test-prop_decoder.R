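# Property decoder: objective selection rules and signal recovery.

test_that("select_objective follows the strict ratio rule", {
  mk <- function(ratio) {
    n_pos <- round(ratio * 300); n_neg <- 300
    data <- data.frame(id = as.character(seq_len(n_pos + n_neg)),
                       smiles = "CC",
                       label = c(rep(1, n_pos), rep(0, n_neg)))
    prop_task("t", "classification", data,
              rep("train", nrow(data)))
  }
  # boundary values go to the else branch (strictly "more than"/"less than")
  cases <- list(c(0.2, "auprc"), c(1 / 3, "auroc"), c(1, "auroc"),
                c(3, "auroc"), c(4, "auprc"))
  for (cs in cases) {
    expect_equal(select_objective(mk(as.numeric(cs[1])))$metric, cs[2],
                 info = paste("ratio", cs[1]))
  }
  reg <- prop_task("r", "regression",
                   data.frame(id = "1", smiles = "CC", label = 0.5),
                   "train")
  expect_equal(select_objective(reg), list(loss = "mse", metric = "spearman"))
  # degenerate single-class labels
  one_class <- prop_task("o", "classification",
                         data.frame(id = c("1", "2"), smiles = "CC",
                                    label = c(1, 1)), rep("train", 2))
  expect_error(select_objective(one_class), "single-class")
  # non-binary classification labels rejected at task construction
  expect_error(prop_task("x", "classification",
                         data.frame(id = "1", smiles = "C", label = 0.3),
                         "train"), "0/1")
})

test_that("auprc behaves at its anchors", {
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_lt(auprc(c(0.1, 0.2, 0.9, 0.8), c(1, 1, 0, 0)), 0.6)
})

# shared setup: frozen random encoder, labels built from a linear
# functional of its encodings (the recovery oracle)
prop_setup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lib <- gen_library(120, seed = 31)
    graphs <- lapply(attr(lib, "molecules"), featurize)
    enc_cfg <- encoder_config(n_layers = 2, node_dim = 16)
    ep <- encoder_init(enc_cfg, new_rng(31))
    enc <- encode(graphs, ep, enc_cfg)
    rng <- new_rng(32)
    w <- rng_norm(rng, 16)
    z <- scale(enc %*% w)[, 1]
    part <- rep("train", 120)
    part[81:100] <- "validation"; part[101:120] <- "test"
    cache <<- list(lib = lib, graphs = graphs, enc_cfg = enc_cfg, ep = ep,
                   z = z, part = part, rng = rng)
    cache
  }
})

test_that("decoder recovers a linear functional of the encodings", {
  s <- prop_setup()
  noise <- rng_norm(s$rng, 120, sd = 0.1)
  y_cls <- as.integer(s$z + noise > median(s$z))
  task <- prop_task("cls", "classification",
                    data.frame(id = s$lib$id, smiles = s$lib$smiles,
                               label = y_cls), s$part)
  fit <- fit_property(task, s$graphs, s$ep, s$enc_cfg,
                      decoder_config(size = "small"), seed = 1)
  expect_gte(fit$test_score, 0.95)

  y_reg <- tanh(s$z) + rng_norm(s$rng, 120, sd = 0.05)
  task_r <- prop_task("reg", "regression",
                      data.frame(id = s$lib$id, smiles = s$lib$smiles,
                                 label = y_reg), s$part)
  fit_r <- fit_property(task_r, s$graphs, s$ep, s$enc_cfg,
                        decoder_config(size = "small"), seed = 1)
  expect_equal(fit_r$objective$metric, "spearman")
  expect_gte(fit_r$test_score, 0.8)
})

test_that("shuffled labels give chance-level test AUROC", {
  s <- prop_setup()
  y <- as.integer(s$z > median(s$z))
  aucs <- vapply(1:5, function(sd_i) {
    rngp <- new_rng(100 + sd_i)
    yp <- y[rng_sample(rngp, 120)]
    task <- prop_task("shuf", "classification",
                      data.frame(id = s$lib$id, smiles = s$lib$smiles,
                                 label = yp), s$part)
    fit <- fit_property(task, s$graphs, s$ep, s$enc_cfg,
                        decoder_config(size = "small"), seed = sd_i)
    fit$test_score
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("fine-tuning improves or maintains fit on training data", {
  s <- prop_setup()
  y <- as.integer(s$z > median(s$z))
  task <- prop_task("ft", "classification",
                    data.frame(id = s$lib$id, smiles = s$lib$smiles,
                               label = y), s$part)
  fit <- fit_property(task, s$graphs, s$ep, s$enc_cfg,
                      decoder_config(size = "small", fine_tune_encoder = TRUE),
                      seed = 2)
  expect_true(fit$fine_tuned)
  expect_gte(fit$validation_score, 0.8)
  # fine-tuned encoder parameters actually moved
  expect_false(identical(fit$encoder, s$ep))
})

test_that("predict_property returns bounded scores and reports bad rows", {
  s <- prop_setup()
  y <- as.integer(s$z > median(s$z))
  task <- prop_task("p", "classification",
                    data.frame(id = s$lib$id, smiles = s$lib$smiles,
                               label = y), s$part)
  fit <- fit_property(task, s$graphs, s$ep, s$enc_cfg,
                      decoder_config(size = "small"), seed = 3)
  out <- predict_property(fit, s$graphs[1:10])
  expect_true(all(out$score > 0 & out$score < 1))
  expect_false(any(is.na(out$score)))
  # batch prediction equals per-molecule prediction (eval-mode BN)
  singles <- vapply(1:5, function(i) {
    predict_property(fit, s$graphs[i])$score
  }, numeric(1))
  expect_equal(out$score[1:5], singles, tolerance = 1e-12)
  # unparseable SMILES are reported, not dropped
  df <- data.frame(id = c("ok", "bad"), smiles = c("CCO", "C1CC"),
                   stringsAsFactors = FALSE)
  res <- predict_property(fit, df)
  expect_true("bad" %in% res$id)
  expect_true(is.na(res$score[res$id == "bad"]))
  expect_match(attr(res, "errors")[["bad"]], "invalid")
})
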