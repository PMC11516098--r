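# Minimal neural-network kernel: parameter trees, LeakyReLU, batch
# normalization, Kaiming-uniform init, AdamW. Forward/backward passes are
# written out explicitly; gradients are verified against numerical
# differentiation in the test suite.

LRELU_SLOPE <- 0.01

lrelu <- function(x) {
  neg <- x < 0
  x[neg] <- LRELU_SLOPE * x[neg]
  x
}
# backward helper: scales the incoming gradient d by LeakyReLU'(z) in place
dlrelu <- function(d, z) {
  neg <- z < 0
  d[neg] <- LRELU_SLOPE * d[neg]
  d
}
sigmoid <- function(x) 1 / (1 + exp(-x))
# column-wise bias broadcast without the aperm of matrix(byrow = TRUE)
add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Kaiming-uniform init for a fan_in x fan_out linear layer (LeakyReLU gain)
init_linear <- function(fan_in, fan_out, rng) {
  gain <- sqrt(2 / (1 + LRELU_SLOPE^2))
  bound <- gain * sqrt(3 / fan_in)
  list(W = matrix(rng_unif(rng, fan_in * fan_out, -bound, bound),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

init_batchnorm <- function(dim) {
  list(gamma = rep(1, dim), beta = numeric(dim),
       run_mean = numeric(dim), run_var = rep(1, dim))
}

# x: batch x dim. Returns list(out, cache). Training mode uses batch
# statistics and updates running stats in the returned bn; eval mode uses
# frozen running statistics.
bn_forward <- function(bn, x, training = TRUE, momentum = 0.1, eps = 1e-5) {
  n <- nrow(x)
  if (training && n > 1) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    xc <- x - rep(mu, each = n)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = n)
  out <- xhat * rep(bn$gamma, each = n) + rep(bn$beta, each = n)
  list(out = out, bn = bn,
       cache = list(xhat = xhat, inv_sd = inv_sd,
                    training = training && n > 1))
}

# returns list(dx, dgamma, dbeta)
bn_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  m <- nrow(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = m)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = m) -
             xhat * rep(colMeans(dxhat * xhat), each = m)) *
      rep(cache$inv_sd, each = m)
  } else {
    dx <- dxhat * rep(cache$inv_sd, each = m)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- parameter-tree utilities (nested lists of numeric arrays) ---------

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) param_map2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

param_zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, param_zeros_like))
  p * 0
}

#' @keywords internal
adamw_state <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

# One AdamW step over a parameter tree; `grads` must mirror `params`.
# Batch-norm running statistics are not parameters and must not pass
# through here. Single fused traversal: moments and update in one pass.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r[[1]]; m[[i]] <- r[[2]]; v[[i]] <- r[[3]]
      }
      return(list(p, m, v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p, m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r[[2]]; state$v <- r[[3]]
  list(params = r[[1]], state = state)
}
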