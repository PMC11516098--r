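# Graph encoder and projection heads.

test_that("encoding shape, determinism and permutation invariance", {
  rng <- new_rng(42)
  cfg <- encoder_config(n_layers = 2, node_dim = 64)
  ep <- encoder_init(cfg, rng)
  g <- featurize(mol("CC(=O)Nc1ccc(O)cc1", "paracetamol"))
  enc <- encode(g, ep, cfg)
  expect_equal(dim(enc), c(1L, 64L))
  expect_true(all(is.finite(enc)))
  # bitwise-equal deterministic re-run
  expect_identical(enc, encode(g, ep, cfg))
  # atom renumbering leaves the encoding unchanged
  rng2 <- new_rng(43)
  perm <- rng_sample(rng2, nrow(g$node_features))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  g2 <- structure(list(
    node_features = g$node_features[perm, , drop = FALSE],
    edge_features = g$edge_features,
    adjacency = data.frame(a1 = inv[g$adjacency$a1],
                           a2 = inv[g$adjacency$a2])), class = "csmol_graph")
  expect_equal(enc, encode(g2, ep, cfg), tolerance = 1e-6,
               ignore_attr = TRUE)
  # single-node graph: readout of that node, no messages
  g1 <- featurize(mol("C", "methane"))
  expect_true(all(is.finite(encode(g1, ep, cfg))))
  expect_error(encode(list(), ep, cfg), "empty")
})

test_that("parameter count scales as documented with node_dim", {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  n_params <- function(d, L = 2) {
    cfg <- encoder_config(n_layers = L, node_dim = d)
    count(encoder_init(cfg, new_rng(1)))
  }
  expected <- function(d, L = 2) {
    (27 * d + d) +                       # input
      L * ((d + 4) * d + d + d * d + d) +  # msg + self per layer
      (d * d + d) + (d * d + d)          # readout MLP
  }
  expect_equal(n_params(16), expected(16))
  expect_equal(n_params(64), expected(64))
  expect_equal(n_params(32, L = 3), expected(32, L = 3))
})

test_that("encoder/head gradients match numerical differentiation", {
  rng <- new_rng(7)
  cfg <- encoder_config(n_layers = 2, node_dim = 8, readout_hidden = 8)
  ep <- encoder_init(cfg, rng)
  graphs <- lapply(list(mol("CCO"), mol("c1ccccc1"), mol("CC(=O)N")), featurize)
  packed <- csmol:::pack_graphs(graphs)
  hp <- head_init(head_config("MaxSim", rectifier_out = 16,
                              reduction_stages = c(16, 8)), 8, rng)
  y <- c(0.3, 0.9, 0.5); ai <- c(1, 2, 3); bi <- c(2, 3, 1)
  loss_fn <- function(ep, hp) {
    enc <- csmol:::encoder_forward(ep, packed, cfg)$enc
    out <- csmol:::head_forward(hp, cbind(enc[ai, ], enc[bi, ]),
                                training = TRUE)$out
    mean((out - y)^2)
  }
  fo <- csmol:::encoder_forward(ep, packed, cfg)
  hf <- csmol:::head_forward(hp, cbind(fo$enc[ai, ], fo$enc[bi, ]),
                             training = TRUE)
  hb <- csmol:::head_backward(hf$hp, hf$cache, 2 * (hf$out - y) / 3)
  d_enc <- matrix(0, 3, 8)
  for (r in 1:3) {
    d_enc[ai[r], ] <- d_enc[ai[r], ] + hb$dx[r, 1:8]
    d_enc[bi[r], ] <- d_enc[bi[r], ] + hb$dx[r, 9:16]
  }
  eg <- csmol:::encoder_backward(ep, packed, cfg, fo$cache, d_enc)
  num <- function(set, get, ana) {
    v <- get(); idx <- seq_len(min(5, length(v)))
    for (i in idx) {
      h <- 1e-5
      v1 <- v; v1[i] <- v[i] + h; v2 <- v; v2[i] <- v[i] - h
      s1 <- set(v1); s2 <- set(v2)
      gn <- (loss_fn(s1$ep, s1$hp) - loss_fn(s2$ep, s2$hp)) / (2 * h)
      expect_equal(gn, ana[i], tolerance = 1e-5)
    }
  }
  num(function(v) { e <- ep; e$layers[[1]]$msg$W[] <- v; list(ep = e, hp = hp) },
      function() ep$layers[[1]]$msg$W, as.vector(eg$layers[[1]]$msg$W))
  num(function(v) { e <- ep; e$input$W[] <- v; list(ep = e, hp = hp) },
      function() ep$input$W, as.vector(eg$input$W))
  num(function(v) { h2 <- hp; h2$linears[[1]]$W[] <- v; list(ep = ep, hp = h2) },
      function() hp$linears[[1]]$W, as.vector(hb$grads$linears[[1]]$W))
  num(function(v) { h2 <- hp; h2$bn$gamma[] <- v; list(ep = ep, hp = h2) },
      function() hp$bn$gamma, hb$grads$bn$gamma)
})

test_that("project is sigmoid-bounded, order-sensitive, shape-checked", {
  rng <- new_rng(9)
  hp <- head_init(head_config("MaxSim", rectifier_out = 32,
                              reduction_stages = c(32, 16)), 8, rng)
  a <- rng_norm(rng, 8); b <- rng_norm(rng, 8)
  pab <- project(hp, a, b); pba <- project(hp, b, a)
  expect_true(pab > 0 && pab < 1)
  expect_false(isTRUE(all.equal(pab, pba)))  # ordered concatenation
  # all-zero parameters give sigmoid(0) = 0.5
  hp0 <- hp
  for (i in seq_along(hp0$linears)) {
    hp0$linears[[i]]$W[] <- 0; hp0$linears[[i]]$b[] <- 0
  }
  expect_equal(project(hp0, a, b), 0.5)
  expect_error(project(hp, a, b[1:4]), "mismatch")
})

test_that("ablation head reduces directly to 256 dimensions", {
  rng <- new_rng(4)
  hp <- head_init(head_config("MCS", use_rectifier = FALSE), 8, rng)
  expect_equal(hp$dims, c(16L, 256L, 1L))
  expect_length(hp$linears, 2)
  x <- matrix(rng_norm(rng, 32), 2, 16)
  out <- csmol:::head_forward(hp, x, training = FALSE)$out
  expect_true(all(out > 0 & out < 1))
})

test_that("one optimizer step decreases the batch loss", {
  rng <- new_rng(15)
  cfg <- encoder_config(n_layers = 2, node_dim = 16)
  ep <- encoder_init(cfg, rng)
  hp <- head_init(head_config("MaxSim", rectifier_out = 32,
                              reduction_stages = c(32, 16)), 16, rng)
  graphs <- lapply(list(mol("CCO"), mol("c1ccccc1"), mol("CC(=O)N"),
                        mol("CCCC")), featurize)
  packed <- csmol:::pack_graphs(graphs)
  y <- c(0.2, 0.8, 0.5, 0.9); ai <- c(1, 2, 3, 4); bi <- c(2, 3, 4, 1)
  step_loss <- function(ep, hp) {
    enc <- csmol:::encoder_forward(ep, packed, cfg)$enc
    mean((csmol:::head_forward(hp, cbind(enc[ai, ], enc[bi, ]),
                               training = TRUE)$out - y)^2)
  }
  l0 <- step_loss(ep, hp)
  fo <- csmol:::encoder_forward(ep, packed, cfg)
  hf <- csmol:::head_forward(hp, cbind(fo$enc[ai, ], fo$enc[bi, ]),
                             training = TRUE)
  hb <- csmol:::head_backward(hf$hp, hf$cache, 2 * (hf$out - y) / 4)
  d_enc <- matrix(0, 4, 16)
  for (r in 1:4) {
    d_enc[ai[r], ] <- d_enc[ai[r], ] + hb$dx[r, 1:16]
    d_enc[bi[r], ] <- d_enc[bi[r], ] + hb$dx[r, 17:32]
  }
  eg <- csmol:::encoder_backward(ep, packed, cfg, fo$cache, d_enc)
  tr <- list(encoder = ep, head = csmol:::head_trainable(hp))
  opt <- csmol:::adamw_state(tr)
  upd <- csmol:::adamw_step(tr, list(encoder = eg, head = hb$grads),
                            opt, lr = 1e-3)
  ep2 <- upd$params$encoder
  hp2 <- csmol:::head_set_trainable(hp, upd$params$head)
  expect_lt(step_loss(ep2, hp2), l0)
})
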