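# Contrastive training: weighted MSE over all projection heads, AdamW,
# linear warmup followed by a periodic cosine schedule oscillating
# between the base and minimum learning rates, periodic validation
# (mean Spearman across heads) with early stopping.

#' Training configuration
#'
#' Defaults follow the reference regimen: AdamW at 1e-4, 512 pairs per
#' batch, 30 000 warmup steps starting at 0.1x the base rate, cosine
#' oscillation down to 0.5x with a 10 000-step period, validation every
#' 500 steps, early stop after 50 validations without improvement.
#' `max_steps` bounds desk-scale runs.
#'
#' @param lr base learning rate
#' @param batch_pairs pairs per batch
#' @param warmup_steps,warmup_start_factor linear warmup
#' @param cosine_min_factor,cosine_period_steps cosine schedule
#' @param validate_every_steps,patience_validations early stopping
#' @param head_weights named per-head loss weights (default 1)
#' @param sample_weighting `"uniform"` or `"positive_emphasis"`
#' @param positive_factor up-weight factor for pairs with label MaxSim
#'   above 0.6 under `"positive_emphasis"`
#' @param heads descriptor targets to train heads for
#' @param weight_decay AdamW weight decay
#' @param max_steps hard step cap
#' @param seed integer seed (shuffling and initialization)
#' @export
train_config <- function(lr = 1e-4, batch_pairs = 512L,
                         warmup_steps = 30000L, warmup_start_factor = 0.1,
                         cosine_min_factor = 0.5, cosine_period_steps = 10000L,
                         validate_every_steps = 500L,
                         patience_validations = 50L,
                         head_weights = NULL,
                         sample_weighting = c("uniform", "positive_emphasis"),
                         positive_factor = 4,
                         heads = HEAD_TARGETS,
                         weight_decay = 0,
                         max_steps = Inf,
                         seed = 1) {
  stopifnot(warmup_start_factor > 0, warmup_start_factor <= 1,
            cosine_min_factor > 0, cosine_min_factor <= 1,
            patience_validations >= 1)
  w <- setNames(rep(1, length(heads)), heads)
  if (!is.null(head_weights)) w[names(head_weights)] <- head_weights
  list(lr = lr, batch_pairs = as.integer(batch_pairs),
       warmup_steps = as.integer(warmup_steps),
       warmup_start_factor = warmup_start_factor,
       cosine_min_factor = cosine_min_factor,
       cosine_period_steps = as.integer(cosine_period_steps),
       validate_every_steps = as.integer(validate_every_steps),
       patience_validations = as.integer(patience_validations),
       head_weights = w,
       sample_weighting = match.arg(sample_weighting),
       positive_factor = positive_factor,
       heads = heads, weight_decay = weight_decay,
       max_steps = max_steps, seed = seed)
}

#' Learning rate at a training step
#'
#' Linear warmup from `warmup_start_factor * lr` at step 0 to `lr` at
#' `warmup_steps`; afterwards a periodic cosine oscillation between `lr`
#' and `cosine_min_factor * lr` with period `cosine_period_steps`.
#'
#' @param step step counter (0-based)
#' @param cfg a [train_config()]
#' @export
lr_at_step <- function(step, cfg) {
  stopifnot(all(step >= 0))
  lr <- cfg$lr
  out <- numeric(length(step))
  warm <- step < cfg$warmup_steps
  out[warm] <- lr * (cfg$warmup_start_factor +
    (1 - cfg$warmup_start_factor) * step[warm] / cfg$warmup_steps)
  t <- step[!warm] - cfg$warmup_steps
  lr_min <- cfg$cosine_min_factor * lr
  out[!warm] <- lr_min + (lr - lr_min) *
    (1 + cos(2 * pi * t / cfg$cosine_period_steps)) / 2
  out
}

#' Weighted MSE loss over projection heads
#'
#' `sum_h head_weight_h * mean_i( w_i * (pred_hi - label_hi)^2 )` with
#' uniform sample weights by default; the positive-emphasis scheme
#' up-weights pairs whose label MaxSim exceeds 0.6.
#'
#' @param preds named list (by head) of prediction vectors
#' @param labels data.frame holding one column per enabled head (and
#'   `MaxSim` when positive-emphasis weighting is on)
#' @param cfg a [train_config()]
#' @export
css_loss <- function(preds, labels, cfg) {
  sw <- rep(1, nrow(labels))
  if (cfg$sample_weighting == "positive_emphasis") {
    sw[labels$MaxSim > 0.6] <- cfg$positive_factor
  }
  total <- 0
  for (h in cfg$heads) {
    if (is.null(labels[[h]])) stop("missing label column for head ", h,
                                   call. = FALSE)
    total <- total + cfg$head_weights[[h]] *
      mean(sw * (preds[[h]] - labels[[h]])^2)
  }
  total
}

validation_score <- function(ep, hps, enc_cfg, graphs, labels, cfg) {
  packed <- pack_graphs(graphs[unique(c(labels$id_a, labels$id_b))])
  ids <- unique(c(labels$id_a, labels$id_b))
  enc <- encoder_forward(ep, packed, enc_cfg)$enc
  rownames(enc) <- ids
  x <- cbind(enc[labels$id_a, , drop = FALSE], enc[labels$id_b, , drop = FALSE])
  rho <- vapply(cfg$heads, function(h) {
    p <- head_forward(hps[[h]], x, training = FALSE)$out
    if (sd(p) == 0 || sd(labels[[h]]) == 0) return(0)
    cor(p, labels[[h]], method = "spearman")
  }, numeric(1))
  mean(rho)
}

#' Train the encoder and projection heads on a labeled pair table
#'
#' @param graphs named list of `csmol_graph` covering every molecule id
#'   in `labels`
#' @param labels labeled pair table (columns `id_a`, `id_b`, one column
#'   per enabled head)
#' @param partition character vector per label row: `"train"` /
#'   `"validation"` (other values ignored)
#' @param enc_cfg an [encoder_config()]
#' @param cfg a [train_config()]
#' @param head_cfgs optional named list of [head_config()]s; defaults to
#'   rectifier heads for `cfg$heads`
#' @param verbose print validation progress
#' @return a checkpoint: list with `encoder` and `heads` parameters (best
#'   validation state), configs, `history` (per-validation scores) and a
#'   training manifest
#' @export
train_css <- function(graphs, labels, partition, enc_cfg,
                      cfg = train_config(), head_cfgs = NULL,
                      verbose = FALSE) {
  train_rows <- which(partition == "train")
  val_rows <- which(partition == "validation")
  if (length(train_rows) == 0 || length(val_rows) == 0) {
    stop("need non-empty train and validation partitions", call. = FALSE)
  }
  rng <- new_rng(cfg$seed)
  ep <- encoder_init(enc_cfg, rng)
  if (is.null(head_cfgs)) {
    head_cfgs <- setNames(lapply(cfg$heads, head_config), cfg$heads)
  }
  hps <- lapply(head_cfgs, head_init, enc_dim = enc_cfg$node_dim, rng = rng)
  trainable <- list(encoder = ep, heads = lapply(hps, head_trainable))
  opt <- adamw_state(trainable)
  val_labels <- labels[val_rows, , drop = FALSE]
  best <- list(score = -Inf, encoder = ep, hps = hps, step = 0L)
  since_best <- 0L
  history <- list()
  step <- 0L
  order_idx <- integer(0)
  sw_all <- rep(1, nrow(labels))
  if (cfg$sample_weighting == "positive_emphasis") {
    sw_all[labels$MaxSim > 0.6] <- cfg$positive_factor
  }
  repeat {
    if (length(order_idx) < cfg$batch_pairs) {
      order_idx <- c(order_idx,
                     train_rows[rng_sample(rng, length(train_rows))])
    }
    batch <- order_idx[seq_len(min(cfg$batch_pairs, length(order_idx)))]
    order_idx <- order_idx[-seq_len(min(cfg$batch_pairs, length(order_idx)))]
    blab <- labels[batch, , drop = FALSE]
    ids <- unique(c(blab$id_a, blab$id_b))
    packed <- pack_graphs(graphs[ids])
    fo <- encoder_forward(ep, packed, enc_cfg)
    enc <- fo$enc
    ai <- match(blab$id_a, ids); bi <- match(blab$id_b, ids)
    x <- cbind(enc[ai, , drop = FALSE], enc[bi, , drop = FALSE])
    B <- nrow(blab)
    sw <- sw_all[batch]
    D <- enc_cfg$node_dim
    head_grads <- list()
    loss_val <- 0
    dx_sum <- matrix(0, B, 2L * D)
    for (h in cfg$heads) {
      hf <- head_forward(hps[[h]], x, training = TRUE)
      hps[[h]] <- hf$hp  # running BN stats
      resid <- hf$out - blab[[h]]
      loss_val <- loss_val + cfg$head_weights[[h]] * mean(sw * resid^2)
      d_out <- cfg$head_weights[[h]] * 2 * sw * resid / B
      hb <- head_backward(hps[[h]], hf$cache, d_out)
      head_grads[[h]] <- hb$grads
      dx_sum <- dx_sum + hb$dx
    }
    d_enc <- scatter_rows(dx_sum[, 1:D, drop = FALSE], ai, length(ids)) +
      scatter_rows(dx_sum[, (D + 1):(2 * D), drop = FALSE], bi, length(ids))
    if (!is.finite(loss_val)) {
      stop("NaN/Inf loss at step ", step, "; aborting", call. = FALSE)
    }
    eg <- encoder_backward(ep, packed, enc_cfg, fo$cache, d_enc)
    grads <- list(encoder = eg, heads = head_grads[cfg$heads])
    trainable <- list(encoder = ep, heads = lapply(hps, head_trainable))
    upd <- adamw_step(trainable, grads, opt, lr = lr_at_step(step, cfg),
                      weight_decay = cfg$weight_decay)
    opt <- upd$state
    ep <- upd$params$encoder
    for (h in cfg$heads) {
      hps[[h]] <- head_set_trainable(hps[[h]], upd$params$heads[[h]])
    }
    step <- step + 1L
    if (step %% cfg$validate_every_steps == 0 || step >= cfg$max_steps) {
      score <- validation_score(ep, hps, enc_cfg, graphs, val_labels, cfg)
      history[[length(history) + 1]] <- data.frame(
        step = step, loss = loss_val, val_spearman = score)
      if (verbose) {
        message(sprintf("step %d  lr %.2e  loss %.5f  val spearman %.4f",
                        step, lr_at_step(step, cfg), loss_val, score))
      }
      if (score > best$score) {
        best <- list(score = score, encoder = ep, hps = hps, step = step)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= cfg$patience_validations || step >= cfg$max_steps) break
    }
  }
  list(
    encoder_config = enc_cfg, head_configs = head_cfgs, train_config = cfg,
    encoder = best$encoder, heads = best$hps,
    best_score = best$score, best_step = best$step, last_step = step,
    history = do.call(rbind, history),
    manifest = list(seed = cfg$seed, n_train = length(train_rows),
                    n_validation = length(val_rows))
  )
}

#' Predict CSS descriptors for molecule pairs with a trained checkpoint
#'
#' @param ckpt checkpoint from [train_css()]
#' @param graphs named list of `csmol_graph`
#' @param pairs data.frame with `id_a`, `id_b`
#' @return data.frame of per-head predictions
#' @export
predict_css <- function(ckpt, graphs, pairs) {
  ids <- unique(c(pairs$id_a, pairs$id_b))
  enc <- encode(graphs[ids], ckpt$encoder, ckpt$encoder_config)
  rownames(enc) <- ids
  x <- cbind(enc[pairs$id_a, , drop = FALSE], enc[pairs$id_b, , drop = FALSE])
  out <- lapply(names(ckpt$heads), function(h) {
    head_forward(ckpt$heads[[h]], x, training = FALSE)$out
  })
  setNames(as.data.frame(out), names(ckpt$heads))
}

#' Export molecule encodings as a delimited table
#'
#' @param ckpt checkpoint from [train_css()]
#' @param graphs named list of `csmol_graph`
#' @param path output CSV path (`id` column + one column per dimension)
#' @export
export_encodings <- function(ckpt, graphs, path) {
  enc <- encode(graphs, ckpt$encoder, ckpt$encoder_config)
  df <- data.frame(id = names(graphs), enc)
  names(df) <- c("id", paste0("e", seq_len(ncol(enc))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Save / load a training checkpoint
#'
#' @param ckpt checkpoint list
#' @param path file path
#' @export
save_checkpoint <- function(ckpt, path) saveRDS(ckpt, path)

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
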