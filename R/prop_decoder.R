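# Downstream property modeling (QSAR/ADMET): a projection-head-style
# decoder over single-molecule encodings, with optional encoder
# fine-tuning. Loss and validation metric are selected from the task
# type: classification uses the mean of binary cross-entropy and MSE
# with AUPRC (class ratio > 3 or < 1/3) or AUROC; regression uses MSE
# with Spearman.

#' Define a property-prediction task
#'
#' @param name task label
#' @param task_type `"classification"` (binary 0/1 labels) or
#'   `"regression"`
#' @param data data.frame with `id`, `smiles`, `label`
#' @param partition character vector per row: train/validation/test
#' @export
prop_task <- function(name, task_type = c("classification", "regression"),
                      data, partition) {
  task_type <- match.arg(task_type)
  stopifnot(nrow(data) == length(partition))
  if (task_type == "classification") {
    if (!all(data$label %in% c(0, 1))) {
      stop("classification labels must be 0/1", call. = FALSE)
    }
  } else if (!all(is.finite(data$label))) {
    stop("regression labels must be finite", call. = FALSE)
  }
  list(name = name, task_type = task_type, data = data,
       partition = partition)
}

#' Loss and validation metric for a property task
#'
#' Classification: loss = (BCE + MSE)/2; metric = AUPRC when the
#' positive/negative ratio is strictly above 3 or strictly below 1/3,
#' else AUROC. Regression: loss = MSE, metric = Spearman.
#'
#' @param task a [prop_task()]
#' @return list `loss`, `metric`
#' @export
select_objective <- function(task) {
  if (task$task_type == "regression") {
    return(list(loss = "mse", metric = "spearman"))
  }
  y <- task$data$label[task$partition == "train"]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate single-class training labels", call. = FALSE)
  }
  ratio <- n_pos / n_neg
  metric <- if (ratio > 3 || ratio < 1 / 3) "auprc" else "auroc"
  list(loss = "bce_mse", metric = metric)
}

#' Area under the precision-recall curve (average precision)
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @export
auprc <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / sum(y)
}

#' Decoder configuration
#'
#' @param size `"small"` or `"large"` preset (hidden widths, learning
#'   rate, batch size and epochs scale with the dataset); `"auto"` picks
#'   by training-set size against `size_threshold`
#' @param fine_tune_encoder jointly update the encoder parameters
#' @param size_threshold rows above which `"auto"` selects `"large"`
#' @param expand_factor rectifier expansion of the encoding (default 5)
#' @export
decoder_config <- function(size = c("auto", "small", "large"),
                           fine_tune_encoder = FALSE,
                           size_threshold = 5000L,
                           expand_factor = 5L) {
  list(size = match.arg(size), fine_tune_encoder = isTRUE(fine_tune_encoder),
       size_threshold = as.integer(size_threshold),
       expand_factor = as.integer(expand_factor))
}

decoder_preset <- function(size) {
  if (size == "small") {
    list(stages = c(128L, 64L), lr = 1e-3, batch = 32L, epochs = 100L,
         patience = 15L)
  } else {
    list(stages = c(512L, 256L, 128L), lr = 2e-3, batch = 256L,
         epochs = 30L, patience = 8L)
  }
}

decoder_init <- function(enc_dim, stages, expand_factor, rng) {
  dims <- c(enc_dim, expand_factor * enc_dim, stages, 1L)
  lin <- list()
  for (i in seq_len(length(dims) - 1L)) {
    lin[[i]] <- init_linear(dims[i], dims[i + 1L], rng)
  }
  list(linears = lin, bn = init_batchnorm(dims[2]), dims = dims)
}

# gradient of the selected loss wrt the final pre-activation (logit for
# classification, raw output for regression), averaged over the batch
prop_loss_grad <- function(loss, z_out, y) {
  B <- length(y)
  if (loss == "bce_mse") {
    p <- sigmoid(z_out)
    l <- mean((-(y * log(pmax(p, 1e-12)) +
                   (1 - y) * log(pmax(1 - p, 1e-12))) + (p - y)^2) / 2)
    dz <- ((p - y) + 2 * (p - y) * p * (1 - p)) / (2 * B)
  } else {
    l <- mean((z_out - y)^2)
    dz <- 2 * (z_out - y) / B
  }
  list(loss = l, dz = dz)
}

prop_metric <- function(metric, scores, y) {
  switch(metric,
         auroc = auroc(scores, y == 1),
         auprc = auprc(scores, y),
         spearman = if (sd(scores) == 0) 0 else
           cor(scores, y, method = "spearman"))
}

#' Fit a property predictor on molecule encodings
#'
#' Trains the decoder with AdamW (preset learning rate/batch/epochs by
#' dataset size); with `fine_tune_encoder` the encoder parameters update
#' jointly. The best-validation checkpoint is retained and the held-out
#' test metric reported.
#'
#' @param task a [prop_task()]
#' @param graphs named list of `csmol_graph` covering the task molecules
#' @param encoder_params,enc_cfg encoder (e.g. from a [train_css()]
#'   checkpoint)
#' @param cfg a [decoder_config()]
#' @param seed integer seed
#' @param verbose print per-epoch progress
#' @return a predictor: decoder + (possibly fine-tuned) encoder +
#'   objective + metrics
#' @export
fit_property <- function(task, graphs, encoder_params, enc_cfg,
                         cfg = decoder_config(), seed = 1, verbose = FALSE) {
  obj <- select_objective(task)
  parts <- task$partition
  tr <- which(parts == "train"); va <- which(parts == "validation")
  te <- which(parts == "test")
  if (length(tr) == 0 || length(va) == 0) {
    stop("need train and validation partitions", call. = FALSE)
  }
  size <- if (cfg$size == "auto") {
    if (length(tr) > cfg$size_threshold) "large" else "small"
  } else cfg$size
  preset <- decoder_preset(size)
  rng <- new_rng(seed)
  D <- enc_cfg$node_dim
  dp <- decoder_init(D, preset$stages, cfg$expand_factor, rng)
  ep <- encoder_params
  final <- if (task$task_type == "classification") "sigmoid" else "linear"
  ids <- task$data$id
  # frozen-encoder path: encode everything once
  enc_all <- NULL
  if (!cfg$fine_tune_encoder) {
    enc_all <- encode(graphs[ids], ep, enc_cfg)
    rownames(enc_all) <- ids
  }
  get_scores <- function(rows, dp, ep) {
    x <- if (is.null(enc_all)) {
      encode(graphs[ids[rows]], ep, enc_cfg)
    } else enc_all[rows, , drop = FALSE]
    head_forward(dp, x, training = FALSE, final = final)$out
  }
  trainable <- if (cfg$fine_tune_encoder) {
    list(decoder = head_trainable(dp), encoder = ep)
  } else list(decoder = head_trainable(dp))
  opt <- adamw_state(trainable)
  best <- list(score = -Inf, dp = dp, ep = ep)
  since <- 0L
  y <- task$data$label
  for (epoch in seq_len(preset$epochs)) {
    ord <- tr[rng_sample(rng, length(tr))]
    for (start in seq(1, length(ord), by = preset$batch)) {
      rows <- ord[start:min(start + preset$batch - 1L, length(ord))]
      if (length(rows) < 2) next
      if (cfg$fine_tune_encoder) {
        packed <- pack_graphs(graphs[ids[rows]])
        fo <- encoder_forward(ep, packed, enc_cfg)
        x <- fo$enc
      } else {
        x <- enc_all[rows, , drop = FALSE]
      }
      hf <- head_forward(dp, x, training = TRUE, final = final)
      dp <- hf$hp
      z_out <- if (final == "sigmoid") {
        cache_z <- hf$cache$zs[[length(dp$linears)]][, 1]
        cache_z
      } else hf$out
      lg <- prop_loss_grad(obj$loss, z_out, y[rows])
      if (!is.finite(lg$loss)) stop("NaN loss in property training",
                                    call. = FALSE)
      hb <- head_backward(dp, hf$cache, lg$dz, wrt = "logit")
      grads <- list(decoder = hb$grads)
      if (cfg$fine_tune_encoder) {
        grads$encoder <- encoder_backward(ep, packed, enc_cfg, fo$cache, hb$dx)
      }
      trainable <- if (cfg$fine_tune_encoder) {
        list(decoder = head_trainable(dp), encoder = ep)
      } else list(decoder = head_trainable(dp))
      upd <- adamw_step(trainable, grads, opt, lr = preset$lr)
      opt <- upd$state
      dp <- head_set_trainable(dp, upd$params$decoder)
      if (cfg$fine_tune_encoder) ep <- upd$params$encoder
    }
    val_score <- prop_metric(obj$metric, get_scores(va, dp, ep), y[va])
    if (verbose) message(sprintf("epoch %d  val %s %.4f", epoch,
                                 obj$metric, val_score))
    if (val_score > best$score) {
      best <- list(score = val_score, dp = dp, ep = ep); since <- 0L
    } else {
      since <- since + 1L
      if (since >= preset$patience) break
    }
  }
  test_score <- if (length(te) > 0) {
    prop_metric(obj$metric, get_scores(te, best$dp, best$ep), y[te])
  } else NA_real_
  structure(list(
    task_name = task$name, task_type = task$task_type,
    objective = obj, size = size,
    decoder = best$dp, encoder = best$ep, enc_cfg = enc_cfg,
    fine_tuned = cfg$fine_tune_encoder,
    validation_score = best$score, test_score = test_score
  ), class = "csmol_predictor")
}

#' Predict property scores for molecules
#'
#' @param predictor from [fit_property()]
#' @param graphs named list of `csmol_graph` (or a data.frame with
#'   `smiles`, `id` — unparseable rows are reported in the result, not
#'   dropped)
#' @return data.frame `id`, `score` (`NA` score + `error` column entry
#'   for unparseable input)
#' @export
predict_property <- function(predictor, graphs) {
  errors <- character(0)
  if (is.data.frame(graphs)) {
    parsed <- list()
    for (i in seq_len(nrow(graphs))) {
      m <- tryCatch(parse_molecule(graphs$smiles[i], graphs$id[i]),
                    error = function(e) conditionMessage(e))
      if (is.character(m)) {
        errors[graphs$id[i]] <- m
      } else {
        parsed[[graphs$id[i]]] <- featurize(m)
      }
    }
    graphs <- parsed
  }
  final <- if (predictor$task_type == "classification") "sigmoid" else "linear"
  x <- encode(graphs, predictor$encoder, predictor$enc_cfg)
  s <- head_forward(predictor$decoder, x, training = FALSE, final = final)$out
  out <- data.frame(id = names(graphs), score = s, stringsAsFactors = FALSE)
  if (length(errors) > 0) {
    out <- rbind(out, data.frame(id = names(errors), score = NA_real_,
                                 stringsAsFactors = FALSE))
    attr(out, "errors") <- errors
  }
  out
}
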