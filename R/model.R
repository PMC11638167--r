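# ---- model: full decoder = MFF front-end + DGACN + softmax head ------------

#' Full decoder configuration
#'
#' Bundles the input geometry (C electrodes, T samples per segment), the
#' multi-scale feature extractor and the graph attention settings, and the
#' number of classes.
#'
#' @param C Number of electrodes (default 64).
#' @param T Samples per segment (default 160, i.e. 1 s at 160 Hz).
#' @param n_classes Number of motor-imagery classes (default 4).
#' @param mff An [mff_config()].
#' @param gat A [gat_config()].
#' @return A `danet_config` list.
#' @export
danet_config <- function(C = 64, T = 160, n_classes = 4,
                         mff = mff_config(), gat = gat_config()) {
  structure(list(C = as.integer(C), T = as.integer(T),
                 n_classes = as.integer(n_classes), mff = mff, gat = gat),
            class = "danet_config")
}

#' Initialize a decoder model
#'
#' Creates Glorot-uniform initialized parameters (biases zero) for the
#' configured architecture and seeds the electrode graph with the
#' inverse-distance prior of `layout`. The model is an ordinary list and
#' can be saved with `saveRDS()`.
#'
#' @param layout A [montage_layout()]; its electrode count must equal
#'   `config$C` and its order is the node order of every graph matrix.
#' @param config A [danet_config()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `danet_model` with elements `config`, `layout`,
#'   `params` (flat named list of arrays), `adj` (an [adjacency_state()]),
#'   and `g3_mean` (epoch statistics, NULL until trained).
#' @export
danet_model <- function(layout, config = danet_config(), seed = 1) {
  stopifnot(inherits(layout, "montage_layout"))
  if (n_channels(layout) != config$C) {
    stop("layout has ", n_channels(layout), " electrodes but config$C = ",
         config$C)
  }
  E <- build_prior_adjacency(layout)
  params <- with_seed(seed, {
    p <- mff_init_params(config$mff)
    p <- c(p, gat_init_params(config$gat, in_dim = config$T))
    d <- config$gat$hidden_dim
    p[["clf.W"]] <- glorot(c(config$C * d, config$n_classes),
                           config$C * d, config$n_classes)
    p[["clf.b"]] <- numeric(config$n_classes)
    p
  })
  structure(list(config = config, layout = layout, params = params,
                 adj = adjacency_state(E), g3_mean = NULL),
            class = "danet_model")
}

#' @export
print.danet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<danet_model> C=", x$config$C, " T=", x$config$T,
      " classes=", x$config$n_classes, ", ", np, " parameters, ",
      x$adj$update_count, " adjacency update(s)\n", sep = "")
  invisible(x)
}

# reshape a batch (B x C x T slice of a segment array) into the node-major
# conv layout: (C*B*T) x 1 with row u + (b-1)C + (t-1)CB
batch_to_m0 <- function(Xb) {
  d <- dim(Xb)                       # B, C, T
  matrix(aperm(Xb, c(2, 1, 3)), ncol = 1)
}

# Full batched forward pass. Returns probabilities, loss pieces and (when
# with_cache) everything needed for the backward pass and feature taps.
danet_forward_batch <- function(model, Xb, labels = NULL,
                                with_cache = FALSE) {
  cfg <- model$config
  C <- cfg$C; B <- dim(Xb)[1]; T <- dim(Xb)[3]
  stopifnot(dim(Xb)[2] == C, T == cfg$T)
  M0 <- batch_to_m0(Xb)
  mff <- mff_forward_batch(M0, model$params, cfg$mff, R = C * B)
  Gm <- matrix(mff$pooled, C * B, T)          # node-major feature matrix
  LB <- adj_log_bias(model$adj$P)
  gat_caches <- vector("list", cfg$gat$n_layers)
  for (l in seq_len(cfg$gat$n_layers)) {
    gl <- gat_layer_forward_batch(Gm, model$params, cfg$gat, l, LB, C)
    gat_caches[[l]] <- gl$cache
    Gm <- gl$out
  }
  d <- cfg$gat$hidden_dim
  # per-segment flattened node features (B x C*d), electrode fastest
  Fb <- t(matrix(aperm(array(Gm, c(C, B, d)), c(1, 3, 2)), C * d, B))
  logits <- sweep(Fb %*% model$params[["clf.W"]], 2,
                  model$params[["clf.b"]], "+")
  mx <- apply(logits, 1, max)
  Z <- exp(logits - mx)
  probs <- Z / rowSums(Z)
  loss <- NULL
  if (!is.null(labels)) {
    py <- probs[cbind(seq_len(B), labels + 1L)]
    loss <- -mean(log(pmax(py, 1e-300)))
  }
  out <- list(probs = probs, loss = loss, G3 = Gm, Fb = Fb,
              XMFF = mff$pooled)
  if (with_cache) {
    out$cache <- list(M0 = M0, mff = mff$cache, gat = gat_caches,
                      Fb = Fb, probs = probs, B = B)
  }
  out
}

# Full batched backward pass (cross-entropy). Returns flat gradient list.
danet_backward_batch <- function(model, cache, labels) {
  cfg <- model$config
  C <- cfg$C; B <- cache$B; d <- cfg$gat$hidden_dim
  probs <- cache$probs
  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  dLogits <- (probs - Y) / B
  grads <- list(
    "clf.W" = crossprod(cache$Fb, dLogits),
    "clf.b" = colSums(dLogits))
  dFb <- dLogits %*% t(model$params[["clf.W"]])     # B x C*d
  dGm <- matrix(aperm(array(t(dFb), c(C, d, B)), c(1, 3, 2)), C * B, d)
  for (l in rev(seq_len(cfg$gat$n_layers))) {
    gb <- gat_layer_backward_batch(dGm, cache$gat[[l]], model$params,
                                   cfg$gat, l, C)
    grads <- c(grads, gb$grads)
    dGm <- gb$dGm
  }
  dPooled <- as.vector(dGm)                         # (C*B*T) vector
  grads <- c(grads, mff_backward_batch(dPooled, cache$mff, model$params,
                                       cfg$mff, R = C * B))
  grads
}

#' Predict class probabilities for segments
#'
#' @param object A trained [danet_model()].
#' @param segments An `eeg_segments` container (or N x C x T array).
#' @param batch_size Segments per forward batch (default 64).
#' @param ... Unused.
#' @return N x n_classes matrix of class probabilities.
#' @export
predict.danet_model <- function(object, segments, batch_size = 64, ...) {
  X <- if (inherits(segments, "eeg_segments")) segments$data else segments
  N <- dim(X)[1]
  out <- matrix(0, N, object$config$n_classes)
  for (at in seq(1, N, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, N)
    out[idx, ] <- danet_forward_batch(object, X[idx, , , drop = FALSE])$probs
  }
  out
}

#' Extract intermediate features at a named stage
#'
#' Taps the per-segment features after the multi-scale frequency module
#' (`"mff"`: flattened C x T pooled features) or after the graph attention
#' module (`"dgacn"`: flattened C x hidden node embeddings) -- the two
#' stages whose class structure the interpretability tools visualize.
#'
#' @param model A [danet_model()].
#' @param segments An `eeg_segments` container (or N x C x T array).
#' @param stage `"mff"` or `"dgacn"`.
#' @param batch_size Segments per forward batch.
#' @return N x F feature matrix.
#' @export
stage_features <- function(model, segments, stage = c("dgacn", "mff"),
                           batch_size = 64) {
  stage <- match.arg(stage)
  X <- if (inherits(segments, "eeg_segments")) segments$data else segments
  N <- dim(X)[1]; C <- model$config$C; T <- model$config$T
  Fdim <- if (stage == "mff") C * T else C * model$config$gat$hidden_dim
  out <- matrix(0, N, Fdim)
  for (at in seq(1, N, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, N)
    fw <- danet_forward_batch(model, X[idx, , , drop = FALSE])
    B <- length(idx)
    if (stage == "mff") {
      # pooled vector is (C*B*T); regroup to B x (C*T)
      arr <- array(fw$XMFF, c(C, B, T))
      out[idx, ] <- t(matrix(aperm(arr, c(1, 3, 2)), C * T, B))
    } else {
      out[idx, ] <- fw$Fb
    }
  }
  out
}
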