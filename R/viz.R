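# ---- viz: interpretability exports -----------------------------------------

#' t-SNE embedding of intermediate features with silhouette score
#'
#' Extracts per-segment features at the requested stage ([stage_features()]),
#' embeds them in 2-D with [tsne_embed()] and attaches the class labels,
#' plus the mean silhouette width of the classes in the embedding -- a
#' quantitative stand-in for "the classes look better separated": higher
#' after the graph attention module than after the frequency module when
#' the spatial structure carries class information.
#'
#' @param model A trained [danet_model()].
#' @param segments `eeg_segments` with labels (>= 2 classes present).
#' @param stage `"mff"` or `"dgacn"`.
#' @param seed Seed for the embedding initialization.
#' @param perplexity,n_iter Passed to [tsne_embed()].
#' @param max_points Optional cap on segments (subsampled deterministically
#'   from `seed`) to keep the quadratic embedding affordable.
#' @return List with `embedding` (N x 2), `labels`, `silhouette` (mean
#'   silhouette width over the embedded points), `stage`.
#' @export
tsne_features <- function(model, segments, stage = c("dgacn", "mff"),
                          seed = 1, perplexity = 30, n_iter = 500,
                          max_points = NULL) {
  stage <- match.arg(stage)
  labels <- segments$labels
  if (length(unique(labels)) < 2) {
    stop("need at least two classes for a stage embedding")
  }
  keep <- seq_along(labels)
  if (!is.null(max_points) && length(keep) > max_points) {
    keep <- with_seed(seed, sort(sample(keep, max_points)))
  }
  X <- stage_features(model, segments[keep], stage)
  Y <- tsne_embed(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  sil <- cluster::silhouette(as.integer(labels[keep]) + 1L, stats::dist(Y))
  list(embedding = Y, labels = labels[keep],
       silhouette = mean(sil[, "sil_width"]), stage = stage)
}

#' Silhouette of stage features without embedding
#'
#' Mean silhouette width computed directly on the high-dimensional stage
#' features (no t-SNE), useful as a deterministic separability measure.
#'
#' @inheritParams tsne_features
#' @return Scalar mean silhouette width.
#' @export
stage_silhouette <- function(model, segments, stage = c("dgacn", "mff")) {
  stage <- match.arg(stage)
  X <- stage_features(model, segments, stage)
  sil <- cluster::silhouette(as.integer(segments$labels) + 1L, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Export adjacency snapshots for connectivity rendering
#'
#' Writes, for each requested update index of a training run's adjacency
#' history, a triplet of plain-text files: `adjacency_<i>.csv` (the full
#' weighted matrix), and BrainNet-Viewer-convention `adjacency_<i>.node`
#' (columns x y z color size label) / `adjacency_<i>.edge` (whitespace-
#' delimited C x C matrix) with edges below the percentile threshold
#' zeroed, so only the strongest connections render as discrete links.
#' Node size is the thresholded connection strength (degree), color the
#' node index.
#'
#' @param history List of P matrices (`model$adj$history`).
#' @param layout The [montage_layout()] supplying node coordinates/labels.
#' @param indices Update indices to export (default all).
#' @param threshold_pct Percentile (0-100) of positive edge weights below
#'   which edges are dropped (default 90).
#' @param out_dir Output directory (created if missing).
#' @return Data frame listing the files written, invisibly.
#' @export
export_adjacency_series <- function(history, layout, indices = NULL,
                                    threshold_pct = 90, out_dir = ".") {
  if (length(history) == 0) stop("empty adjacency history")
  if (is.null(indices)) indices <- seq_along(history)
  if (any(indices < 1 | indices > length(history))) {
    stop("update index out of range 1..", length(history))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- NULL
  for (i in indices) {
    P <- history[[i]]
    w <- P[upper.tri(P) & P > 0]
    thr <- if (length(w)) stats::quantile(w, threshold_pct / 100) else Inf
    Pt <- P
    Pt[Pt < thr] <- 0
    if (threshold_pct >= 100) Pt[] <- 0   # boundary: nothing survives
    base <- file.path(out_dir, sprintf("adjacency_%03d", i))
    utils::write.csv(P, paste0(base, ".csv"), row.names = TRUE)
    node <- data.frame(layout$coords, color = seq_along(layout$names),
                       size = rowSums(Pt), label = layout$names)
    utils::write.table(node, paste0(base, ".node"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(unname(Pt), paste0(base, ".edge"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- rbind(files, data.frame(
      index = i, csv = paste0(base, ".csv"), node = paste0(base, ".node"),
      edge = paste0(base, ".edge")))
  }
  invisible(files)
}

#' Scatter plot of a stage embedding
#'
#' @param emb Result of [tsne_features()].
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot_stage_embedding <- function(emb, ...) {
  cls <- as.integer(emb$labels)
  graphics::plot(emb$embedding, col = cls + 2L, pch = 19, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = sprintf("%s features (silhouette %.3f)",
                                toupper(emb$stage), emb$silhouette), ...)
  graphics::legend("topright", legend = sort(unique(cls)),
                   col = sort(unique(cls)) + 2L, pch = 19, cex = 0.8)
  invisible(emb)
}
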