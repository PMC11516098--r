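# Projection heads: predict one CSS/MCS descriptor from the ordered
# concatenation of two encoding vectors.
#
# Rectifier head: linear to 5x the (concatenated) input width, batch
# normalization, linear to `rectifier_out`, then a reduction cascade with
# LeakyReLU between all linear layers, ending in a single sigmoid unit.
# The ablation variant replaces the rectifier with a direct reduction to
# 256 dimensions.

HEAD_TARGETS <- c("MaxSim", "MaxDistance", "MaxOverlap", "MaxAggregation",
                  "CrossSim", "CrossDistance", "CrossOverlap",
                  "CrossAggregation", "MCS")

#' Projection-head configuration
#'
#' @param target_name descriptor this head predicts (one of
#'   `HEAD_TARGETS`)
#' @param rectifier_expand_factor expansion of the concatenated input
#'   (default 5)
#' @param rectifier_out width after the rectifier (default 1024)
#' @param reduction_stages widths of the reduction cascade
#' @param use_rectifier `FALSE` selects the ablation variant (direct
#'   reduction to 256)
#' @export
head_config <- function(target_name, rectifier_expand_factor = 5L,
                        rectifier_out = 1024L,
                        reduction_stages = c(1024L, 512L, 256L, 128L),
                        use_rectifier = TRUE) {
  stopifnot(target_name %in% HEAD_TARGETS)
  list(target_name = target_name,
       rectifier_expand_factor = as.integer(rectifier_expand_factor),
       rectifier_out = as.integer(rectifier_out),
       reduction_stages = as.integer(reduction_stages),
       use_rectifier = isTRUE(use_rectifier))
}

#' Initialize head parameters for encodings of length `enc_dim`
#'
#' @param cfg a [head_config()]
#' @param enc_dim encoding length D (head input is 2D)
#' @param rng internal RNG stream
#' @export
head_init <- function(cfg, enc_dim, rng) {
  d_in <- 2L * enc_dim
  if (cfg$use_rectifier) {
    d_exp <- cfg$rectifier_expand_factor * d_in
    # d_in -> 5*d_in (BN) -> rectifier_out -> reduction cascade -> 1
    dims <- c(d_in, d_exp, cfg$rectifier_out, cfg$reduction_stages[-1], 1L)
  } else {
    dims <- c(d_in, 256L, 1L)
  }
  lin <- list()
  for (i in seq_len(length(dims) - 1L)) {
    lin[[i]] <- init_linear(dims[i], dims[i + 1L], rng)
  }
  list(linears = lin, bn = init_batchnorm(dims[2]), dims = dims)
}

# Forward: x = cbind(enc_a, enc_b), batch x 2D. BN sits after the first
# linear; LeakyReLU between all layers; sigmoid output (`final = "linear"`
# skips the sigmoid, used by regression decoders).
head_forward <- function(hp, x, training = TRUE, final = "sigmoid") {
  zs <- vector("list", length(hp$linears))
  as_ <- list(); cur <- x
  n_lin <- length(hp$linears)
  bn_cache <- NULL; bn_out <- NULL; out <- NULL
  for (i in seq_len(n_lin)) {
    L <- hp$linears[[i]]
    z <- add_bias(cur %*% L$W, L$b)
    zs[[i]] <- z
    if (i == 1) {
      bf <- bn_forward(hp$bn, z, training = training)
      hp$bn <- bf$bn
      bn_cache <- bf$cache
      z <- bf$out
      bn_out <- z
    }
    if (i < n_lin) {
      cur <- lrelu(z)
      as_[[i]] <- cur
    } else {
      out <- if (final == "sigmoid") sigmoid(z[, 1]) else z[, 1]
    }
  }
  list(out = out, hp = hp,
       cache = list(x = x, zs = zs, as_ = as_, bn_cache = bn_cache,
                    bn_out = bn_out))
}

# Backward from d_out (batch vector). `wrt = "output"`: d_out is the
# gradient wrt the sigmoid output; `wrt = "logit"`: wrt the final
# pre-activation (used for linear outputs and fused losses).
# Returns list(grads, dx).
head_backward <- function(hp, cache, d_out, wrt = "output") {
  n_lin <- length(hp$linears)
  z_last <- cache$zs[[n_lin]][, 1]
  dz <- if (wrt == "output") {
    p <- sigmoid(z_last)
    matrix(d_out * p * (1 - p), ncol = 1)
  } else {
    matrix(d_out, ncol = 1)
  }
  g <- vector("list", n_lin)
  dbn <- list(dgamma = NULL, dbeta = NULL)
  for (i in rev(seq_len(n_lin))) {
    inp <- if (i == 1) cache$x else cache$as_[[i - 1]]
    g[[i]] <- list(W = crossprod(inp, dz), b = colSums(dz))
    dcur <- tcrossprod(dz, hp$linears[[i]]$W)
    if (i > 1) {
      z_prev <- if (i - 1 == 1) cache$bn_out else cache$zs[[i - 1]]
      dz <- dlrelu(dcur, z_prev)
      if (i - 1 == 1) {
        bb <- bn_backward(dz, cache$bn_cache, hp$bn$gamma)
        dbn$dgamma <- bb$dgamma; dbn$dbeta <- bb$dbeta
        dz <- bb$dx
      }
    } else {
      dx <- dcur
    }
  }
  list(grads = list(linears = g,
                    bn = list(gamma = dbn$dgamma, beta = dbn$dbeta)),
       dx = dx)
}

# trainable head parameters as a tree (for AdamW); running stats excluded
head_trainable <- function(hp) {
  list(linears = hp$linears, bn = list(gamma = hp$bn$gamma, beta = hp$bn$beta))
}

head_set_trainable <- function(hp, tree) {
  hp$linears <- tree$linears
  hp$bn$gamma <- tree$bn$gamma
  hp$bn$beta <- tree$bn$beta
  hp
}

#' Predict one descriptor for a pair of encodings
#'
#' Input order matters: `project(head, a, b)` differs from
#' `project(head, b, a)` in general, as required for the directional
#' descriptors.
#'
#' @param hp head parameters ([head_init()])
#' @param enc_a,enc_b encoding vectors (or matrices, one row per pair)
#' @return predicted value(s) in (0, 1)
#' @export
project <- function(hp, enc_a, enc_b) {
  if (is.null(dim(enc_a))) enc_a <- matrix(enc_a, 1)
  if (is.null(dim(enc_b))) enc_b <- matrix(enc_b, 1)
  if (ncol(enc_a) != ncol(enc_b)) {
    stop("encoding length mismatch: ", ncol(enc_a), " vs ", ncol(enc_b),
         call. = FALSE)
  }
  head_forward(hp, cbind(enc_a, enc_b), training = FALSE)$out
}
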