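small_cfg <- function(...) {
  synthetic_config(trials_per_class = 6, ...)
}

test_that("generation is deterministic and validates centers", {
  lay <- load_builtin_montage()
  a <- generate_dataset(small_cfg(seed = 5), lay)
  b <- generate_dataset(small_cfg(seed = 5), lay)
  expect_identical(a$data, b$data)
  expect_error(generate_dataset(small_cfg(class_centers =
    c("C4", "C3", "CZ", "NOPE")), lay), "NOPE")
  expect_error(synthetic_config(class_bands = list(c(8, 12), c(8, 12),
                                                   c(18, 26), c(10, 90))),
               "inside")
})

test_that("class oscillation peaks inside the configured band", {
  lay <- load_builtin_montage()
  cfg <- small_cfg(snr_db = 15, subject_freq_jitter_hz = 0, seed = 2)
  tr <- generate_dataset(cfg, lay)
  for (k in c(1, 3)) {
    band <- cfg$class_bands[[k]]
    center <- cfg$class_centers[k]
    sel <- which(tr$labels == k - 1)[1:3]
    for (i in sel) {
      x <- tr$data[i, which(lay$names == center), ]
      sp <- stats::spec.pgram(stats::ts(x, frequency = cfg$fs), plot = FALSE,
                              taper = 0, detrend = FALSE)
      peak <- sp$freq[which.max(sp$spec)]
      expect_gte(peak, band[1] - 0.5)
      expect_lte(peak, band[2] + 0.5)
    }
  }
})

test_that("class power is focussed near the configured center electrode", {
  lay <- load_builtin_montage()
  cfg <- small_cfg(snr_db = 15, subject_gain_sd = 0, seed = 3)
  tr <- generate_dataset(cfg, lay)
  D <- montage_distances(lay)
  for (k in seq_len(4)) {
    band <- cfg$class_bands[[k]]
    feats <- dganet:::bandpower_features(tr, list(band))
    in_class <- colMeans(feats[tr$labels == k - 1, , drop = FALSE])
    rest <- colMeans(feats[tr$labels != k - 1, , drop = FALSE])
    top <- which.max(in_class - rest)
    near <- order(D[cfg$class_centers[k], ])[1:3]   # center + 2 closest
    expect_true(top %in% near)
  }
})

test_that("separability grows with SNR and vanishes without signal", {
  lay <- load_builtin_montage()
  scores <- sapply(1:3, function(seed) {
    sapply(c(-20, 0, 20), function(snr) {
      class_separability(generate_dataset(small_cfg(snr_db = snr,
                                                    seed = seed), lay))
    })
  })
  # strict ordering per seed: higher SNR separates better
  for (s in 1:3) {
    expect_lt(scores[1, s], scores[2, s])
    expect_lt(scores[2, s], scores[3, s])
  }
  noise <- class_separability(generate_dataset(small_cfg(snr_db = -100,
                                                         seed = 1), lay))
  expect_lt(noise, 0.2)   # scatter-ratio noise floor ~ (K-1)/(N-K)
})

test_that("identical data relabeled into fake classes is inseparable", {
  lay <- load_builtin_montage()
  tr <- generate_dataset(synthetic_config(classes = 1, class_centers = "C3",
                                          class_bands = list(c(8, 12)),
                                          trials_per_class = 12, seed = 4),
                         lay)
  fake <- tr
  fake$labels <- rep(0:1, 12)[seq_len(n_items(tr))]
  expect_lt(class_separability(fake), 0.1)
  expect_error(class_separability(tr), "two classes")
})

test_that("band-power oracle recovers classes at high SNR, not at -100 dB", {
  lay <- load_builtin_montage()
  # two distant foci with disjoint bands: an easy two-class problem
  easy <- synthetic_config(trials_per_class = 15, classes = 2,
                           class_centers = c("C3", "OZ"),
                           class_bands = list(c(8, 12), c(20, 26)),
                           snr_db = 20, seed = 6)
  tr <- generate_dataset(easy, lay)
  acc <- bandpower_oracle_cv(tr, easy$class_bands)
  expect_gt(acc, 0.9)
  dead <- generate_dataset(small_cfg(snr_db = -100, seed = 7), lay)
  acc0 <- bandpower_oracle_cv(dead, list(c(8, 12), c(18, 26)))
  # chance is 0.25; binomial 99% half-width at n = 24 trials is ~0.23
  expect_lt(abs(acc0 - 0.25), 0.25)
})
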