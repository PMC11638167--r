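make_trials <- function(n_per_class = 3, classes = 4, C = 4, L = 640,
                        subject = 1, seed = 1) {
  set.seed(seed)
  n <- n_per_class * classes
  eeg_trials(array(rnorm(n * C * L), c(n, C, L)),
             rep(seq_len(classes) - 1L, each = n_per_class),
             subject = subject, fs = 160)
}

test_that("sliding window yields the protocol's segment counts", {
  tr <- make_trials(1, 1, C = 2, L = 640)
  segs <- sliding_window(tr, window = 160, stride = 20)
  expect_equal(n_items(segs), 25)          # 4-s trial at 160 Hz
  # exact fit: one segment equal to the trial
  tr1 <- make_trials(1, 1, C = 2, L = 160)
  segs1 <- sliding_window(tr1, 160, 20)
  expect_equal(n_items(segs1), 1)
  expect_equal(segs1$data[1, , ], tr1$data[1, , ])
  # L = 200: starts 0, 20, 40
  tr2 <- make_trials(1, 1, C = 2, L = 200)
  segs2 <- sliding_window(tr2, 160, 20)
  expect_equal(n_items(segs2), 3)
  expect_equal(segs2$window, 0:2)
  for (w in 0:2) {
    expect_identical(segs2$data[w + 1, , ],
                     tr2$data[1, , w * 20 + seq_len(160)])
  }
})

test_that("window count conservation: 84 trials give 2100 segments", {
  tr <- make_trials(21, 4, C = 2, L = 640)
  segs <- sliding_window(tr)
  expect_equal(n_items(segs), 84 * 25)
  expect_equal(n_items(segs), 2100)
})

test_that("segments inherit label and provenance bit-exactly", {
  tr <- make_trials(2, 2, C = 3, L = 240, subject = 9)
  segs <- sliding_window(tr, 160, 40)
  nw <- (240 - 160) %/% 40 + 1
  expect_equal(segs$labels, rep(tr$labels, each = nw))
  expect_equal(segs$trial, rep(tr$trial, each = nw))
  expect_true(all(segs$subject == 9))
  i <- 7  # arbitrary segment: must equal its parent slice exactly
  tid <- segs$trial[i]; w <- segs$window[i]
  expect_identical(segs$data[i, , ],
                   tr$data[which(tr$trial == tid), , w * 40 + seq_len(160)])
})

test_that("oversized window is rejected", {
  tr <- make_trials(1, 1, C = 2, L = 100)
  expect_error(sliding_window(tr, 160, 20), "exceeds")
})

test_that("split is stratified with floor rounding at the trial level", {
  tr <- make_trials(84, 4, C = 2, L = 32)
  sp <- split_trials(tr, 0.8, seed = 11)
  expect_equal(n_items(sp$train), 268)     # 4 * floor(0.8 * 84)
  expect_equal(n_items(sp$test), 68)
  expect_equal(unname(table(sp$train$labels)), rep(67L, 4),
               ignore_attr = TRUE)
  # no trial on both sides
  expect_length(intersect(sp$train$trial, sp$test$trial), 0)
})

test_that("split is deterministic in the seed and guards its inputs", {
  tr <- make_trials(5, 4, C = 2, L = 32)
  a <- split_trials(tr, 0.8, seed = 3)
  b <- split_trials(tr, 0.8, seed = 3)
  expect_identical(a$train$trial, b$train$trial)
  expect_error(split_trials(tr, 1.0), "strictly inside")
  expect_error(split_trials(tr, 0), "strictly inside")
  # a class represented by a single trial cannot be split
  expect_error(split_trials(tr[c(1, 2, 6)], 0.8), "at least 2")
})

test_that("windows of one trial never leak across a split", {
  tr <- make_trials(6, 4, C = 2, L = 320)
  sp <- split_trials(tr, 0.7, seed = 5)
  seg_tr <- sliding_window(sp$train)
  seg_te <- sliding_window(sp$test)
  expect_length(intersect(unique(seg_tr$trial), unique(seg_te$trial)), 0)
})

test_that("archives round-trip containers", {
  tr <- make_trials(2, 2, C = 3, L = 64)
  path <- withr::local_tempfile(fileext = ".rds")
  write_archive(tr, path)
  tr2 <- read_archive(path)
  expect_identical(tr2$data, tr$data)
  expect_identical(tr2$labels, tr$labels)
})

test_that("bind_trials concatenates and enforces matching shapes", {
  a <- make_trials(2, 2, C = 3, L = 64, subject = 1, seed = 1)
  b <- make_trials(2, 2, C = 3, L = 64, subject = 2, seed = 2)
  ab <- bind_trials(a, b)
  expect_equal(n_items(ab), n_items(a) + n_items(b))
  bad <- make_trials(1, 2, C = 4, L = 64, subject = 3)
  expect_error(bind_trials(a, bad), "share channel")
})
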