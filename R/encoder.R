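# WLN-style message-passing graph encoder.
#
# Each round, every node aggregates messages from its neighbors — a
# learned linear map of (neighbor node features ++ incident bond
# features) through LeakyReLU — sums them, and combines the sum with a
# linear transform of its own features. The readout is a per-node MLP
# followed by the arithmetic mean over nodes, giving one vector of length
# `node_dim` per molecule. Sum/mean aggregation makes the encoding
# invariant to atom renumbering.

#' Encoder configuration
#'
#' @param n_layers message-passing rounds (default 4)
#' @param node_dim node feature width and encoding length (default 2048;
#'   desk-scale experiments use 64)
#' @param readout_hidden hidden width of the readout MLP (default
#'   `node_dim`)
#' @export
encoder_config <- function(n_layers = 4L, node_dim = 2048L,
                           readout_hidden = node_dim) {
  stopifnot(n_layers >= 1, node_dim >= 8)
  list(n_layers = as.integer(n_layers), node_dim = as.integer(node_dim),
       readout_hidden = as.integer(readout_hidden))
}

#' Initialize encoder parameters
#'
#' @param cfg an [encoder_config()]
#' @param rng internal RNG stream (Kaiming-uniform init)
#' @export
encoder_init <- function(cfg, rng) {
  d <- cfg$node_dim
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(msg = init_linear(d + EDGE_FEATURE_DIM, d, rng),
         self = init_linear(d, d, rng))
  })
  list(
    input = init_linear(NODE_FEATURE_DIM, d, rng),
    layers = layers,
    readout1 = init_linear(d, cfg$readout_hidden, rng),
    readout2 = init_linear(cfg$readout_hidden, d, rng)
  )
}

# Pack a list of csmol_graph into one block ("batched") graph.
# Directed edges: each bond contributes both directions.
pack_graphs <- function(graphs) {
  n_per <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, n_per[-length(n_per)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- integer(0); dst <- integer(0); E <- NULL
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$adjacency) > 0) {
      a <- g$adjacency$a1 + offs[i]; b <- g$adjacency$a2 + offs[i]
      src <- c(src, a, b); dst <- c(dst, b, a)
      E <- rbind(E, g$edge_features, g$edge_features)
    }
  }
  list(X = X, src = src, dst = dst,
       E = if (is.null(E)) matrix(0, 0, EDGE_FEATURE_DIM) else E,
       graph_id = rep(seq_along(graphs), n_per), n_per = n_per)
}

# scatter-add rows of `m` (one per directed edge) onto their target nodes
scatter_rows <- function(m, index, n_rows) {
  out <- matrix(0, n_rows, ncol(m))
  if (nrow(m) > 0) {
    agg <- rowsum(m, group = index)
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

# Forward pass over a packed batch; keeps every intermediate needed for
# the backward pass.
encoder_forward <- function(params, packed, cfg) {
  X <- packed$X
  nT <- nrow(X)
  z0 <- add_bias(X %*% params$input$W, params$input$b)
  H <- lrelu(z0)
  cache <- list(z0 = z0, H = list(H))
  zs_msg <- list(); zs_node <- list(); msgs_in <- list()
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    if (length(packed$src) > 0) {
      Min <- cbind(H[packed$src, , drop = FALSE], packed$E)
      zm <- add_bias(Min %*% lp$msg$W, lp$msg$b)
      Medge <- lrelu(zm)
      Mnode <- scatter_rows(Medge, packed$dst, nT)
    } else {
      Min <- matrix(0, 0, cfg$node_dim + EDGE_FEATURE_DIM)
      zm <- matrix(0, 0, cfg$node_dim)
      Mnode <- matrix(0, nT, cfg$node_dim)
    }
    zn <- add_bias(H %*% lp$self$W, lp$self$b) + Mnode
    H <- lrelu(zn)
    msgs_in[[l]] <- Min; zs_msg[[l]] <- zm; zs_node[[l]] <- zn
    cache$H[[l + 1]] <- H
  }
  zr1 <- add_bias(H %*% params$readout1$W, params$readout1$b)
  R1 <- lrelu(zr1)
  R2 <- add_bias(R1 %*% params$readout2$W, params$readout2$b)
  enc <- rowsum(R2, packed$graph_id) / packed$n_per
  cache$zs_msg <- zs_msg; cache$zs_node <- zs_node; cache$msgs_in <- msgs_in
  cache$zr1 <- zr1; cache$R1 <- R1
  list(enc = enc, cache = cache)
}

# Backward pass: d_enc is (n_graphs x node_dim); returns gradient tree
# mirroring the parameters.
encoder_backward <- function(params, packed, cfg, cache, d_enc) {
  nT <- nrow(packed$X)
  dR2 <- (d_enc / packed$n_per)[packed$graph_id, , drop = FALSE]
  g <- list()
  g$readout2 <- list(W = crossprod(cache$R1, dR2), b = colSums(dR2))
  dR1 <- tcrossprod(dR2, params$readout2$W)
  dzr1 <- dlrelu(dR1, cache$zr1)
  Hlast <- cache$H[[cfg$n_layers + 1]]
  g$readout1 <- list(W = crossprod(Hlast, dzr1), b = colSums(dzr1))
  dH <- tcrossprod(dzr1, params$readout1$W)
  g$layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    dzn <- dlrelu(dH, cache$zs_node[[l]])
    Hprev <- cache$H[[l]]
    gW_self <- crossprod(Hprev, dzn)
    gb_self <- colSums(dzn)
    dH_prev <- tcrossprod(dzn, lp$self$W)
    if (length(packed$src) > 0) {
      dMedge <- dzn[packed$dst, , drop = FALSE]
      dzm <- dlrelu(dMedge, cache$zs_msg[[l]])
      gW_msg <- crossprod(cache$msgs_in[[l]], dzm)
      gb_msg <- colSums(dzm)
      dMin <- tcrossprod(dzm, lp$msg$W)
      dH_prev <- dH_prev +
        scatter_rows(dMin[, seq_len(cfg$node_dim), drop = FALSE],
                     packed$src, nT)
    } else {
      gW_msg <- lp$msg$W * 0; gb_msg <- lp$msg$b * 0
    }
    g$layers[[l]] <- list(msg = list(W = gW_msg, b = gb_msg),
                          self = list(W = gW_self, b = gb_self))
    dH <- dH_prev
  }
  dz0 <- dlrelu(dH, cache$z0)
  g$input <- list(W = crossprod(packed$X, dz0), b = colSums(dz0))
  g[c("input", "layers", "readout1", "readout2")]
}

#' Encode molecules into fixed-length vectors
#'
#' @param graphs a list of `csmol_graph` (see [featurize()]), or a single
#'   graph
#' @param params encoder parameters ([encoder_init()] or from a trained
#'   checkpoint)
#' @param cfg the matching [encoder_config()]
#' @return matrix (n_molecules x node_dim)
#' @export
encode <- function(graphs, params, cfg) {
  if (inherits(graphs, "csmol_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) stop("empty graph list", call. = FALSE)
  for (g in graphs) {
    if (nrow(g$node_features) == 0) stop("empty graph", call. = FALSE)
  }
  packed <- pack_graphs(graphs)
  encoder_forward(params, packed, cfg)$enc
}
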