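# ---- low-level neural-network kernels (dense-algebra, BLAS-backed) ---------
#
# Layout conventions used throughout the model code:
#  * A batch of B segments (C channels x T samples) is stored "node-major"
#    as matrices whose row index is  u + (b-1)*C  (electrode fastest), so a
#    (C*B) x F matrix holds per-node feature vectors for the whole batch.
#  * Temporal convolutions see the batch as a (C*B*T) x D matrix whose row
#    index is  u + (b-1)*C + (t-1)*C*B ; a shift along time is then a shift
#    by whole row-blocks of size C*B, which turns 1-D convolution into a
#    handful of shifted GEMMs (one per kernel tap).

# 1-D same-padding convolution along time, weights shared across electrodes.
# M: (R*T) x Din with R rows per time step; W: k x Din x Dout; b: Dout.
# The compiled kernel takes the weights as a (Din x Dout x k) cube.
conv1d_forward <- function(M, W, b, R) {
  cpp_conv1d_forward(M, aperm(W, c(2, 3, 1)), b, as.integer(R))
}

# returns list(dM, dW, db); set want_dM = FALSE for the first layer
conv1d_backward <- function(M, W, dOut, R, want_dM = TRUE) {
  out <- cpp_conv1d_backward(M, aperm(W, c(2, 3, 1)), dOut,
                             as.integer(R), want_dM)
  out$dW <- aperm(out$dW, c(3, 1, 2))
  out$db <- drop(out$db)
  out
}


glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Adam with optional decoupled-from-schedule L2 (PyTorch-style weight decay
# added to the raw gradient). params/grads: flat named lists of arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# grad-norm diagnostic used by the NaN-loss abort
grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
}
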