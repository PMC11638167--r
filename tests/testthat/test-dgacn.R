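gat_toy <- function(C = 4, Fin = 3, seed = 1,
                    cfg = gat_config(n_layers = 1, heads = 2,
                                     hidden_dim = 3)) {
  set.seed(seed)
  list(cfg = cfg,
       params = dganet:::gat_init_params(cfg, Fin),
       G = matrix(rnorm(C * Fin), C, Fin))
}

toy_adj <- function(P) {
  E <- P
  st <- adjacency_state(structure(E, class = c("prior_adjacency", "matrix")))
  st$P <- unclass(P)
  st
}

test_that("attention rows are distributions over each neighborhood", {
  t <- gat_toy()
  P <- unclass(build_prior_adjacency(toy_layout(4)))
  adj <- toy_adj(P)
  out <- gat_layer(t$G, adj, t$params, t$cfg, 1)
  for (A in out$alpha) {
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-9)
    expect_true(all(A >= 0))
  }
})

test_that("a single neighbor with equal logits is weighted by log P exactly", {
  # two-term softmax with additive log bias: alpha_v / alpha_self = P_uv
  cfg <- gat_config(n_layers = 1, heads = 1, hidden_dim = 2)
  params <- dganet:::gat_init_params(cfg, 2)
  params[["gat.l1.q1.as"]][] <- 0     # all raw logits equal (zero)
  params[["gat.l1.q1.ad"]][] <- 0
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.4
  P[2, 3] <- P[3, 2] <- 0.1   # keep the graph connected but sparse
  adj <- toy_adj(P)
  G <- matrix(rnorm(6), 3, 2)
  out <- gat_layer(G, adj, params, cfg, 1)
  A <- out$alpha[[1]]
  expect_equal(A[1, 2] / A[1, 1], 0.4, tolerance = 1e-6)
  expect_equal(A[3, 2] / A[3, 3], 0.1, tolerance = 1e-6)
  expect_equal(A[1, 3], 0)    # edge absent from P stays absent
})

test_that("layer output matches a brute-force per-node loop", {
  for (seed in 1:4) {
    t <- gat_toy(C = 4, Fin = 3, seed = seed)
    set.seed(seed + 10)
    P <- matrix(runif(16), 4)
    P <- (P + t(P)) / 2
    diag(P) <- 0
    P[P < 0.3] <- 0           # some missing edges
    adj <- toy_adj(P)
    fast <- gat_layer(t$G, adj, t$params, t$cfg, 1)$G_next
    slow <- naive_gat_layer(t$G, P, t$params, t$cfg, 1)
    expect_equal(fast, slow, tolerance = 1e-6)
  }
})

test_that("graph attention is permutation equivariant", {
  t <- gat_toy(C = 5, Fin = 4,
               cfg = gat_config(n_layers = 1, heads = 2, hidden_dim = 3))
  set.seed(3)
  P <- unclass(build_prior_adjacency(toy_layout(5)))
  perm <- c(4, 2, 5, 1, 3)
  out <- gat_layer(t$G, toy_adj(P), t$params, t$cfg, 1)$G_next
  out_p <- gat_layer(t$G[perm, ], toy_adj(P[perm, perm]),
                     t$params, t$cfg, 1)$G_next
  expect_equal(out_p, out[perm, ], tolerance = 1e-9)
})

test_that("feature similarity follows the softened inverse-distance form", {
  G <- rbind(c(0, 0), c(1, 0), c(0, 0))
  K <- feature_similarity(G, delta = 2, xi = 0.5)
  expect_equal(K[1, 3], 1)               # identical rows
  expect_equal(K[1, 2], 0.5 / (1 + 0.5)) # distance 1 -> 1/3
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 3))
  far <- feature_similarity(rbind(c(0, 0), c(1e6, 0)), 2, 0.5)
  expect_lt(far[1, 2], 1e-10)            # K -> 0+ as distance grows
  expect_gt(far[1, 2], 0)
  expect_error(feature_similarity(rbind(c(NA, 1), c(0, 0))), "finite")
  expect_error(feature_similarity(G, delta = 0), "delta")
})

test_that("adjacency update is E * K^gamma with its limiting cases", {
  E <- unclass(build_prior_adjacency(toy_layout(4)))
  st <- adjacency_state(structure(E, class = c("prior_adjacency", "matrix")))
  set.seed(1)
  G3 <- matrix(rnorm(8), 4, 2)
  # gamma = 0: similarity ignored entirely
  st0 <- update_adjacency(st, G3, gat_config(gamma = 0))
  expect_equal(st0$P, E, tolerance = 1e-12)
  # identical features: K = 1 everywhere
  st1 <- update_adjacency(st, matrix(1, 4, 2), gat_config(gamma = 1))
  expect_equal(st1$P, E, tolerance = 1e-12)
  # elementwise product: E entry 0.8 and K entry 1/3 give 0.8/3
  E2 <- matrix(c(0, 0.8, 0.8, 0), 2)
  st2 <- adjacency_state(structure(E2, class = c("prior_adjacency", "matrix")))
  G2 <- rbind(c(0, 0), c(1, 0))          # distance 1 -> K = 1/3 at xi = 0.5
  st2 <- update_adjacency(st2, G2, gat_config(gamma = 1, delta = 2,
                                              xi = 0.5))
  expect_equal(st2$P[1, 2], 0.8 / 3, tolerance = 1e-12)
  # update bookkeeping
  expect_equal(st2$update_count, 1L)
  expect_length(st2$history, 1)
  expect_error(update_adjacency(st, NULL), "forward pass")
})

test_that("updates never exceed the prior or extend its support", {
  E <- unclass(build_prior_adjacency(toy_layout(6, seed = 2)))
  E[E < 0.4] <- 0                        # sparsify the prior
  st <- adjacency_state(structure(E, class = c("prior_adjacency", "matrix")))
  set.seed(4)
  for (i in 1:5) {
    st <- update_adjacency(st, matrix(rnorm(12), 6, 2),
                           gat_config(gamma = 1.5))
    expect_true(all(st$P >= 0))
    expect_true(all(st$P <= st$E + 1e-12))
    expect_true(all(st$P[st$E == 0] == 0))
    expect_equal(st$P, t(st$P), tolerance = 1e-12)
    expect_equal(unname(diag(st$P)), rep(0, 6))
  }
  expect_equal(st$update_count, 5L)
})

test_that("classifier head is a proper softmax over flattened nodes", {
  set.seed(2)
  params <- list("clf.W" = matrix(rnorm(6 * 4, sd = 0.1), 6, 4),
                 "clf.b" = rnorm(4))
  G <- matrix(rnorm(6), 3, 2)
  p <- classify(G, params)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0))
  params0 <- list("clf.W" = matrix(0, 6, 4), "clf.b" = rep(0, 4))
  expect_equal(classify(G, params0), rep(0.25, 4))
  expect_error(classify(matrix(0, 2, 2), params), "does not match")
})
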