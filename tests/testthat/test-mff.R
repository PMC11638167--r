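tiny_mff <- function() mff_config(kernel_sizes = c(3, 5), depths = c(2, 2),
                                  att_hidden = 4)

init_params <- function(cfg, seed = 1) {
  set.seed(seed)
  dganet:::mff_init_params(cfg)
}

test_that("configuration rejects even kernels and bad depths", {
  expect_error(mff_config(kernel_sizes = c(2, 7, 15)), "odd")
  expect_error(mff_config(kernel_sizes = c(3, 7), depths = c(3, 0)),
               "positive depth")
})

test_that("scale branch preserves the time length and maps zero to zero", {
  cfg <- tiny_mff()
  p <- init_params(cfg)
  x <- matrix(rnorm(4 * 17), 4, 17)
  for (j in 1:2) {
    out <- scale_branch(x, j, p, cfg)
    expect_equal(dim(out), c(4, 17, cfg$depths[j]))
  }
  # zero input with zero biases stays zero through ELU layers
  out0 <- scale_branch(matrix(0, 4, 17), 1, p, cfg)
  expect_equal(max(abs(out0)), 0)
})

test_that("1x1 kernels with unit weights and identity activation pass input through", {
  cfg <- mff_config(kernel_sizes = 1, depths = 1, activation = "identity",
                    residual = FALSE)
  p <- init_params(cfg)
  p[["mff.s1.W1"]][] <- 1; p[["mff.s1.W2"]][] <- 1; p[["mff.s1.W3"]][] <- 1
  p[["mff.s1.b1"]][] <- 0; p[["mff.s1.b2"]][] <- 0; p[["mff.s1.b3"]][] <- 0
  x <- matrix(rnorm(3 * 7), 3, 7)
  out <- scale_branch(x, 1, p, cfg)
  expect_equal(out[, , 1], x, tolerance = 1e-12)
})

test_that("attention weights form a convex combination at every position", {
  cfg <- tiny_mff()
  p <- init_params(cfg, 2)
  stacked <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  res <- channel_attention_pool(stacked, p, cfg)
  expect_equal(apply(res$weights, c(1, 2), sum),
               matrix(1, 3, 5), tolerance = 1e-6)
  # zeroed MLP gives uniform weights and the plain mean
  p0 <- p
  p0[["mff.att.W1"]][] <- 0; p0[["mff.att.b1"]][] <- 0
  p0[["mff.att.W2"]][] <- 0; p0[["mff.att.b2"]][] <- 0
  res0 <- channel_attention_pool(stacked, p0, cfg)
  expect_equal(res0$weights, array(1 / 4, c(3, 5, 4)), tolerance = 1e-12)
  expect_equal(res0$X_MFF, apply(stacked, c(1, 2), mean), tolerance = 1e-12)
})

test_that("forced logits reproduce the closed-form weighted average", {
  # two features, logits (ln 3, 0) -> weights (0.75, 0.25);
  # values (1, 3) pool to 0.75*1 + 0.25*3 = 1.5
  cfg <- mff_config(kernel_sizes = c(1, 1), depths = c(1, 1),
                    att_hidden = 2)
  p <- init_params(cfg)
  p[["mff.att.W1"]][] <- 0; p[["mff.att.b1"]][] <- 0
  p[["mff.att.W2"]][] <- 0
  p[["mff.att.b2"]] <- c(log(3), 0)
  stacked <- array(c(1, 3), c(1, 1, 2))
  res <- channel_attention_pool(stacked, p, cfg)
  expect_equal(drop(res$weights), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(drop(res$X_MFF), 1.5, tolerance = 1e-12)
})

test_that("full forward matches the loop-based reference", {
  cfg <- tiny_mff()
  for (seed in 1:3) {
    p <- init_params(cfg, seed)
    set.seed(seed + 50)
    x <- matrix(rnorm(2 * 8), 2, 8)
    fast <- mff_forward(x, p, cfg)
    slow <- naive_mff(x, p, cfg)
    expect_equal(fast$X_MFF, slow, tolerance = 1e-6)
  }
})

test_that("default geometry yields 64 x 160 x 9 stacked features", {
  cfg <- mff_config()
  expect_equal(dganet:::mff_feature_dim(cfg), 9)
  p <- init_params(cfg)
  x <- matrix(rnorm(64 * 160), 64, 160)
  res <- mff_forward(x, p, cfg)
  expect_equal(dim(res$X_conv), c(64, 160, 9))
  expect_equal(dim(res$X_MFF), c(64, 160))
})

test_that("per-electrode computation commutes with channel permutation", {
  cfg <- tiny_mff()
  p <- init_params(cfg, 9)
  set.seed(9)
  x <- matrix(rnorm(5 * 12), 5, 12)
  perm <- c(3, 1, 5, 2, 4)
  a <- mff_forward(x[perm, ], p, cfg)$X_MFF
  b <- mff_forward(x, p, cfg)$X_MFF[perm, ]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("non-finite inputs are rejected", {
  cfg <- tiny_mff()
  p <- init_params(cfg)
  x <- matrix(rnorm(4 * 8), 4, 8)
  x[2, 3] <- NA
  expect_error(scale_branch(x, 1, p, cfg), "finite")
})
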