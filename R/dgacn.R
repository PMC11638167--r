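# ---- dgacn: dynamic graph attention convolution over electrodes ------------

#' Graph attention network configuration
#'
#' A three-layer multi-head graph attention network over the electrode
#' graph. Attention logits follow the standard additive form
#' `LeakyReLU(a_src' W G_u + a_dst' W G_v)` and are biased additively by
#' `log P_uv` before the softmax, so the current adjacency weight gates
#' each edge multiplicatively inside a proper attention distribution
#' (P -> 0 removes an edge smoothly). Every node has an explicit self-loop
#' whose bias uses weight 1 (log 1 = 0); the adjacency diagonal itself
#' stays 0. Edges absent from the distance prior can never appear.
#'
#' The adjacency is periodically re-weighted during training:
#' `P_uv = E_uv * K_uv^gamma`, where `K` is the node-feature similarity of
#' the third layer's embeddings (see [feature_similarity()]).
#'
#' @param n_layers Number of attention layers (default 3).
#' @param heads Attention heads per layer (default 4).
#' @param hidden_dim Per-head (and per-layer output) feature width
#'   (default 32).
#' @param gamma Exponent on the similarity in the adjacency update
#'   (default 1).
#' @param delta Exponent on the embedding distance inside the similarity
#'   (default 2).
#' @param xi Softening constant of the similarity (default 0.5).
#' @param update_period Epochs between adjacency updates (default 10).
#' @param leaky_slope Negative slope of the attention LeakyReLU
#'   (default 0.2).
#' @return A `gat_config` list.
#' @export
gat_config <- function(n_layers = 3, heads = 4, hidden_dim = 32,
                       gamma = 1, delta = 2, xi = 0.5, update_period = 10,
                       leaky_slope = 0.2) {
  stopifnot(n_layers >= 1, heads >= 1, hidden_dim >= 1,
            gamma >= 0, delta > 0, xi > 0, update_period >= 1)
  structure(list(n_layers = as.integer(n_layers), heads = as.integer(heads),
                 hidden_dim = as.integer(hidden_dim), gamma = gamma,
                 delta = delta, xi = xi,
                 update_period = as.integer(update_period),
                 leaky_slope = leaky_slope),
            class = "gat_config")
}

#' Create the adjacency state from a distance prior
#'
#' Tracks the fixed prior `E`, the current working adjacency `P`
#' (initially equal to `E`), the number of updates applied, and optional
#' snapshots of past `P` matrices for the visualization exports.
#'
#' @param E A [build_prior_adjacency()] matrix.
#' @param keep_history Whether to append a snapshot of `P` at every update
#'   (default TRUE).
#' @return An `adjacency_state` list.
#' @export
adjacency_state <- function(E, keep_history = TRUE) {
  P <- unclass(E)
  structure(list(E = unclass(E), P = P, update_count = 0L,
                 keep_history = isTRUE(keep_history), history = list()),
            class = "adjacency_state")
}

#' @export
print.adjacency_state <- function(x, ...) {
  cat("<adjacency_state> ", nrow(x$P), " nodes, ", x$update_count,
      " update(s), ", sum(x$P > 0) / 2, " undirected edges\n", sep = "")
  invisible(x)
}

gat_init_params <- function(cfg, in_dim) {
  p <- list()
  d <- cfg$hidden_dim
  fin <- in_dim
  for (l in seq_len(cfg$n_layers)) {
    for (q in seq_len(cfg$heads)) {
      p[[sprintf("gat.l%d.q%d.W", l, q)]] <- glorot(c(fin, d), fin, d)
      p[[sprintf("gat.l%d.q%d.as", l, q)]] <- glorot(c(d, 1), d, 1)[, 1]
      p[[sprintf("gat.l%d.q%d.ad", l, q)]] <- glorot(c(d, 1), d, 1)[, 1]
    }
    p[[sprintf("gat.l%d.WO", l)]] <- glorot(c(cfg$heads * d, d),
                                            cfg$heads * d, d)
    p[[sprintf("gat.l%d.bO", l)]] <- numeric(d)
    fin <- d
  }
  p
}

# log-bias matrix with -Inf outside the prior support; diagonal 0 (self-loop
# weight 1). Recomputed whenever P changes.
adj_log_bias <- function(P, eps = 1e-12) {
  LB <- matrix(-Inf, nrow(P), ncol(P))
  LB[P > 0] <- log(P[P > 0] + eps)
  diag(LB) <- 0
  LB
}

# Batched GAT layer forward.
# Gm: (C*B) x Fin node-major; LB: C x C log bias. Returns output plus cache.
gat_layer_forward_batch <- function(Gm, params, cfg, l, LB, C) {
  B <- nrow(Gm) / C
  d <- cfg$hidden_dim
  heads <- vector("list", cfg$heads)
  A <- matrix(0, nrow(Gm), cfg$heads * d)
  for (q in seq_len(cfg$heads)) {
    W <- params[[sprintf("gat.l%d.q%d.W", l, q)]]
    as_ <- params[[sprintf("gat.l%d.q%d.as", l, q)]]
    ad_ <- params[[sprintf("gat.l%d.q%d.ad", l, q)]]
    H <- Gm %*% W
    asrc <- drop(H %*% as_)
    adst <- drop(H %*% ad_)
    outq <- cpp_gat_attention_forward(H, asrc, adst, LB, C,
                                      cfg$leaky_slope)
    heads[[q]] <- list(H = H, asrc = asrc, adst = adst)
    A[, (q - 1L) * d + seq_len(d)] <- outq
  }
  WO <- params[[sprintf("gat.l%d.WO", l)]]
  out <- sweep(A %*% WO, 2, params[[sprintf("gat.l%d.bO", l)]], "+")
  list(out = out, cache = list(Gm = Gm, heads = heads, A = A, LB = LB))
}

# Batched GAT layer backward; recomputes attention from the small cached
# projections instead of storing C x C x B alpha tensors.
gat_layer_backward_batch <- function(dOut, cache, params, cfg, l, C) {
  Gm <- cache$Gm
  B <- nrow(Gm) / C
  d <- cfg$hidden_dim
  LB <- cache$LB
  grads <- list()
  WO <- params[[sprintf("gat.l%d.WO", l)]]
  grads[[sprintf("gat.l%d.WO", l)]] <- crossprod(cache$A, dOut)
  grads[[sprintf("gat.l%d.bO", l)]] <- colSums(dOut)
  dA <- dOut %*% t(WO)
  dGm <- matrix(0, nrow(Gm), ncol(Gm))
  for (q in seq_len(cfg$heads)) {
    hc <- cache$heads[[q]]
    W <- params[[sprintf("gat.l%d.q%d.W", l, q)]]
    as_ <- params[[sprintf("gat.l%d.q%d.as", l, q)]]
    ad_ <- params[[sprintf("gat.l%d.q%d.ad", l, q)]]
    dOutq <- dA[, (q - 1L) * d + seq_len(d), drop = FALSE]
    bw <- cpp_gat_attention_backward(hc$H, hc$asrc, hc$adst, LB, dOutq,
                                     C, cfg$leaky_slope)
    dH <- bw$dH
    dasrc <- drop(bw$dasrc)
    dadst <- drop(bw$dadst)
    dH <- dH + outer(dasrc, as_) + outer(dadst, ad_)
    grads[[sprintf("gat.l%d.q%d.as", l, q)]] <- drop(crossprod(hc$H, dasrc))
    grads[[sprintf("gat.l%d.q%d.ad", l, q)]] <- drop(crossprod(hc$H, dadst))
    grads[[sprintf("gat.l%d.q%d.W", l, q)]] <- crossprod(Gm, dH)
    dGm <- dGm + dH %*% t(W)
  }
  list(dGm = dGm, grads = grads)
}

#' Apply one graph attention layer to a single graph
#'
#' @param G Numeric C x F matrix of node features (rows in montage order).
#' @param adj An [adjacency_state()] (its current `P` gates the edges).
#' @param params Model parameter list.
#' @param cfg A [gat_config()].
#' @param l Layer index (selects the layer's parameters).
#' @return List with `G_next` (C x hidden_dim output features) and
#'   `alpha` (heads-long list of C x C attention matrices; each row sums
#'   to 1 over the node's neighborhood).
#' @export
gat_layer <- function(G, adj, params, cfg = gat_config(), l = 1) {
  stopifnot(is.matrix(G), nrow(G) == nrow(adj$P))
  C <- nrow(G)
  LB <- adj_log_bias(adj$P)
  fwd <- gat_layer_forward_batch(G, params, cfg, l, LB, C)
  alpha <- lapply(seq_len(cfg$heads), function(q) {
    hc <- fwd$cache$heads[[q]]
    preE <- matrix(hc$asrc, C, C) + matrix(hc$adst, C, C, byrow = TRUE)
    softmax_rows(lrelu(preE, cfg$leaky_slope) + LB)
  })
  list(G_next = fwd$out, alpha = alpha)
}

#' Node-feature similarity kernel
#'
#' `K_uv = xi / (||G_u - G_v||_2^delta + xi)`: equal to 1 at zero distance,
#' strictly decreasing in the embedding distance, and bounded in (0, 1], so
#' the updated adjacency `E * K^gamma` can only stay below the prior.
#'
#' @param G3 C x F matrix of layer-3 node embeddings (typically the
#'   per-node mean over a training epoch).
#' @param delta Distance exponent (> 0).
#' @param xi Softening constant (> 0).
#' @return C x C symmetric similarity matrix with unit diagonal.
#' @export
feature_similarity <- function(G3, delta = 2, xi = 0.5) {
  stopifnot(delta > 0, xi > 0)
  if (!all(is.finite(G3))) stop("non-finite node features")
  D <- unname(as.matrix(stats::dist(G3)))
  xi / (D^delta + xi)
}

#' Update the working adjacency from epoch-mean embeddings
#'
#' Re-weights every prior edge by the similarity of the two nodes' current
#' layer-3 embeddings: `P_uv <- E_uv * K_uv^gamma`. Geometrically close
#' electrodes whose learned features agree keep strong connections;
#' dissimilar nodes are attenuated. Since `0 < K <= 1` and `gamma >= 0`,
#' `P` never exceeds the prior and never gains support outside it -- the
#' geometry stays authoritative about which edges may exist.
#'
#' @param adj An [adjacency_state()].
#' @param G3_mean C x F per-node mean of third-layer embeddings over the
#'   most recent training epoch.
#' @param cfg A [gat_config()] supplying `gamma`, `delta`, `xi`.
#' @return The updated [adjacency_state()] (update count incremented,
#'   snapshot appended when history is kept).
#' @export
update_adjacency <- function(adj, G3_mean, cfg = gat_config()) {
  stopifnot(inherits(adj, "adjacency_state"))
  if (is.null(G3_mean)) {
    stop("no layer-3 embedding statistics yet: run a forward pass ",
         "(training epoch) before updating the adjacency")
  }
  K <- feature_similarity(G3_mean, cfg$delta, cfg$xi)
  P <- adj$E * K^cfg$gamma
  diag(P) <- 0
  adj$P <- P
  adj$update_count <- adj$update_count + 1L
  if (adj$keep_history) adj$history[[length(adj$history) + 1L]] <- P
  adj
}

#' Softmax classifier head over flattened node features
#'
#' @param G_final C x F matrix of final-layer node features.
#' @param params Model parameter list with `clf.W` ((C*F) x n_classes) and
#'   `clf.b`.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
classify <- function(G_final, params) {
  feat <- as.vector(G_final)
  W <- params[["clf.W"]]
  if (length(feat) != nrow(W)) {
    stop("feature shape ", length(feat),
         " does not match the trained head (", nrow(W), ")")
  }
  logits <- drop(feat %*% W) + params[["clf.b"]]
  p <- exp(logits - max(logits))
  p / sum(p)
}
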