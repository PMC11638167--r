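# ---- exact t-SNE (O(N^2)) for feature-map visualization --------------------
#
# Standard formulation: Gaussian input affinities with per-point bandwidths
# calibrated to a target perplexity by bisection, symmetrized and
# normalized; Student-t low-dimensional affinities; KL gradient descent
# with momentum and early exaggeration. Intended for the few hundred to few
# thousand segments a visualization uses, where the quadratic cost is
# immaterial.

# conditional distribution row with bandwidth found by bisection
tsne_p_row <- function(d2, perplexity, tol = 1e-5, max_iter = 50) {
  target <- log(perplexity)
  beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
  for (i in seq_len(max_iter)) {
    p <- exp(-d2 * beta)
    sp <- sum(p)
    if (sp == 0) { p[] <- 1 / length(p); break }
    H <- log(sp) + beta * sum(d2 * p) / sp
    if (abs(H - target) < tol) break
    if (H > target) {
      beta_lo <- beta
      beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
    } else {
      beta_hi <- beta
      beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
    }
  }
  p / sum(p)
}

#' 2-D t-SNE embedding (exact)
#'
#' @param X N x D feature matrix.
#' @param perplexity Effective neighborhood size (default 30; capped at
#'   `(N - 1) / 3`).
#' @param n_iter Gradient-descent iterations (default 500).
#' @param seed Integer seed for the random initialization.
#' @param exaggeration Early-exaggeration factor applied for the first
#'   quarter of the iterations (default 12).
#' @param eta Learning rate (default 200).
#' @return N x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 500, seed = 1,
                       exaggeration = 12, eta = 200) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 4) stop("need at least 4 points for a t-SNE embedding")
  perplexity <- min(perplexity, (N - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    idx <- setdiff(seq_len(N), i)
    P[i, idx] <- tsne_p_row(D2[i, idx], perplexity)
  }
  P <- (P + t(P)) / (2 * N)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(N * 2, sd = 1e-4), N, 2)
  })
  G <- matrix(0, N, 2)      # gains
  G[] <- 1
  dY <- matrix(0, N, 2)
  stop_exag <- max(1, round(n_iter / 4))
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    # Student-t affinities
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    G <- pmax(0.01, ifelse(sign(grad) != sign(dY), G + 0.2, G * 0.8))
    dY <- mom * dY - eta * G * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
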