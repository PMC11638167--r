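# ---- mff: multi-scale frequency-domain feature extraction ------------------

#' Multi-scale feature extractor configuration
#'
#' Three parallel temporal-convolution stacks (one per kernel scale) run
#' over each electrode's time course independently; short kernels respond
#' to fast (high-frequency) structure and long kernels to slow structure,
#' so the concatenated stack is a learned multi-band decomposition. Each
#' stack has three layers with a residual connection from the first layer's
#' output into the third layer's pre-activation. A channel-attention MLP
#' then pools the stacked features back to one value per (electrode, time)
#' position via a softmax-weighted average over the feature axis.
#'
#' @param kernel_sizes Odd kernel lengths per scale (default 3, 7, 15).
#' @param depths Per-scale layer depth (feature maps per layer; default 3
#'   for every scale, so the stacked feature axis has length 9). The first
#'   and third layers share this depth so the residual shapes match.
#' @param att_hidden Hidden width of the attention MLP (default 16).
#' @param activation Nonlinearity name (default "elu").
#' @param residual Whether to use the first-to-third layer residual
#'   (default TRUE).
#' @return An `mff_config` list.
#' @export
mff_config <- function(kernel_sizes = c(3, 7, 15), depths = c(3, 3, 3),
                       att_hidden = 16, activation = "elu",
                       residual = TRUE) {
  kernel_sizes <- as.integer(kernel_sizes)
  depths <- as.integer(depths)
  if (length(depths) == 1) depths <- rep(depths, length(kernel_sizes))
  if (any(kernel_sizes < 1) || any(kernel_sizes %% 2 == 0)) {
    stop("kernel sizes must be odd and >= 1 (same-padding symmetry)")
  }
  if (length(depths) != length(kernel_sizes) || any(depths < 1)) {
    stop("depths must give one positive depth per scale")
  }
  structure(list(kernel_sizes = kernel_sizes, depths = depths,
                 att_hidden = as.integer(att_hidden),
                 activation = activation, residual = isTRUE(residual)),
            class = "mff_config")
}

mff_feature_dim <- function(cfg) sum(cfg$depths)

# Glorot-initialized parameter list; names mff.s<j>.W<l>/b<l>, mff.att.*
mff_init_params <- function(cfg) {
  p <- list()
  for (j in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[j]; D <- cfg$depths[j]
    din <- c(1L, D, D)
    for (l in 1:3) {
      p[[sprintf("mff.s%d.W%d", j, l)]] <-
        glorot(c(k, din[l], D), k * din[l], k * D)
      p[[sprintf("mff.s%d.b%d", j, l)]] <- numeric(D)
    }
  }
  Fdim <- mff_feature_dim(cfg); H <- cfg$att_hidden
  p[["mff.att.W1"]] <- glorot(c(Fdim, H), Fdim, H)
  p[["mff.att.b1"]] <- numeric(H)
  p[["mff.att.W2"]] <- glorot(c(H, Fdim), H, Fdim)
  p[["mff.att.b2"]] <- numeric(Fdim)
  p
}

# Batched scale branch. M0: (R*T) x 1 input, R rows per time step.
# Returns activations and pre-activations for backward.
mff_branch_forward <- function(M0, params, j, cfg, R) {
  act <- activation_fun(cfg$activation)
  g <- function(l, what) params[[sprintf("mff.s%d.%s%d", j, what, l)]]
  H1 <- act$f(conv1d_forward(M0, g(1, "W"), g(1, "b"), R))
  H2 <- act$f(conv1d_forward(H1, g(2, "W"), g(2, "b"), R))
  pre3 <- conv1d_forward(H2, g(3, "W"), g(3, "b"), R)
  if (cfg$residual) pre3 <- pre3 + H1
  H3 <- act$f(pre3)
  list(H3 = H3, cache = list(M0 = M0, H1 = H1, H2 = H2, H3 = H3))
}

mff_branch_backward <- function(dH3, cache, params, j, cfg, R) {
  act <- activation_fun(cfg$activation)
  g <- function(l, what) params[[sprintf("mff.s%d.%s%d", j, what, l)]]
  grads <- list()
  dpre3 <- dH3 * act$gout(cache$H3)
  b3 <- conv1d_backward(cache$H2, g(3, "W"), dpre3, R)
  grads[[sprintf("mff.s%d.W3", j)]] <- b3$dW
  grads[[sprintf("mff.s%d.b3", j)]] <- b3$db
  dH2 <- b3$dM
  dpre2 <- dH2 * act$gout(cache$H2)
  b2 <- conv1d_backward(cache$H1, g(2, "W"), dpre2, R)
  grads[[sprintf("mff.s%d.W2", j)]] <- b2$dW
  grads[[sprintf("mff.s%d.b2", j)]] <- b2$db
  dH1 <- b2$dM
  if (cfg$residual) dH1 <- dH1 + dpre3   # residual skip into layer-3 preact
  dpre1 <- dH1 * act$gout(cache$H1)
  b1 <- conv1d_backward(cache$M0, g(1, "W"), dpre1, R, want_dM = FALSE)
  grads[[sprintf("mff.s%d.W1", j)]] <- b1$dW
  grads[[sprintf("mff.s%d.b1", j)]] <- b1$db
  grads
}

# Channel-attention pooling over the feature axis (ELU MLP; compiled).
# Xconv: P x F (P = positions); returns pooled P-vector and weights P x F.
att_pool_forward <- function(Xconv, params, cfg) {
  fw <- cpp_att_pool_forward(Xconv, params[["mff.att.W1"]],
                             params[["mff.att.b1"]],
                             params[["mff.att.W2"]],
                             params[["mff.att.b2"]])
  list(pooled = drop(fw$pooled), Watt = fw$Watt,
       cache = list(Xconv = Xconv, A1 = fw$A1, Watt = fw$Watt,
                    pooled = drop(fw$pooled)))
}

att_pool_backward <- function(dPooled, cache, params, cfg) {
  bw <- cpp_att_pool_backward(dPooled, cache$Xconv, cache$Watt, cache$A1,
                              cache$pooled, params[["mff.att.W1"]],
                              params[["mff.att.W2"]])
  grads <- list(
    "mff.att.W2" = bw$dW2,
    "mff.att.b2" = drop(bw$db2),
    "mff.att.W1" = bw$dW1,
    "mff.att.b1" = drop(bw$db1))
  list(dXconv = bw$dXconv, grads = grads)
}

# Full batched MFF forward. M0: (C*B*T) x 1. Returns pooled vector
# (length C*B*T, same row order) plus caches.
mff_forward_batch <- function(M0, params, cfg, R) {
  branches <- lapply(seq_along(cfg$kernel_sizes), function(j) {
    mff_branch_forward(M0, params, j, cfg, R)
  })
  Xconv <- do.call(cbind, lapply(branches, `[[`, "H3"))
  pool <- att_pool_forward(Xconv, params, cfg)
  list(pooled = pool$pooled, Watt = pool$Watt,
       cache = list(branches = lapply(branches, `[[`, "cache"),
                    pool = pool$cache))
}

mff_backward_batch <- function(dPooled, cache, params, cfg, R) {
  pb <- att_pool_backward(dPooled, cache$pool, params, cfg)
  grads <- pb$grads
  col <- 0L
  for (j in seq_along(cfg$kernel_sizes)) {
    D <- cfg$depths[j]
    dH3 <- pb$dXconv[, col + seq_len(D), drop = FALSE]
    grads <- c(grads, mff_branch_backward(dH3, cache$branches[[j]],
                                          params, j, cfg, R))
    col <- col + D
  }
  grads
}

# ---- exported single-segment views of the same kernels ----------------------

#' Run one temporal-convolution scale branch
#'
#' Applies the three-layer stack of scale `j` to a single C x T segment:
#' 1-D convolutions along time only (weights shared across electrodes, so
#' electrode channels stay independent), same padding throughout, and the
#' first layer's output added to the third layer's pre-activation.
#'
#' @param x Numeric C x T matrix.
#' @param j Scale index.
#' @param params Parameter list from an initialized model (see
#'   [danet_model()]), or `mff_init_params` output.
#' @param cfg An [mff_config()].
#' @return C x T x D array of scale-`j` features.
#' @export
scale_branch <- function(x, j, params, cfg = mff_config()) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  C <- nrow(x); T <- ncol(x)
  M0 <- matrix(as.vector(x), ncol = 1)      # row = u + (t-1)*C
  out <- mff_branch_forward(M0, params, j, cfg, R = C)$H3
  array(out, c(C, T, cfg$depths[j]))
}

#' Channel-attention pooling of stacked multi-scale features
#'
#' A shared two-layer MLP maps the length-F feature vector at every
#' (electrode, time) position to F logits; their softmax (over the feature
#' axis, so weights sum to 1 at each position) defines a convex combination
#' that pools the stack to a single value per position.
#'
#' @param stacked C x T x F feature array.
#' @param params Parameter list containing the `mff.att.*` entries.
#' @param cfg An [mff_config()] (activation of the MLP).
#' @return List with `X_MFF` (C x T pooled features) and `weights`
#'   (C x T x F softmax weights).
#' @export
channel_attention_pool <- function(stacked, params, cfg = mff_config()) {
  if (!all(is.finite(stacked))) stop("non-finite feature values")
  d <- dim(stacked)
  Xconv <- matrix(stacked, d[1] * d[2], d[3])
  pool <- att_pool_forward(Xconv, params, cfg)
  list(X_MFF = matrix(pool$pooled, d[1], d[2]),
       weights = array(pool$Watt, d))
}

#' Full multi-scale frequency feature extraction for one segment
#'
#' Runs every scale branch, concatenates the per-scale feature stacks along
#' the feature axis and pools them with [channel_attention_pool()].
#'
#' @param x Numeric C x T matrix (one EEG segment).
#' @param params Model parameter list.
#' @param cfg An [mff_config()].
#' @return List with `X_conv` (C x T x F stacked features), `X_MFF`
#'   (C x T pooled features) and `weights` (C x T x F attention weights).
#' @export
mff_forward <- function(x, params, cfg = mff_config()) {
  stopifnot(is.matrix(x))
  C <- nrow(x); T <- ncol(x)
  M0 <- matrix(as.vector(x), ncol = 1)
  fwd <- mff_forward_batch(M0, params, cfg, R = C)
  Fdim <- mff_feature_dim(cfg)
  Xconv <- fwd$cache$pool$Xconv
  list(X_conv = array(Xconv, c(C, T, Fdim)),
       X_MFF = matrix(fwd$pooled, C, T),
       weights = array(fwd$Watt, c(C, T, Fdim)))
}
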