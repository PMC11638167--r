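# protocol checks run on a 5-electrode toy geometry so training stays fast;
# the full-geometry learning behavior is covered by the acceptance suite

toy_synth <- function(n_per_class = 6, snr_db = 15, n_subjects = 1,
                      seed = 1, gain_sd = 0.1) {
  lay <- toy_layout(5, seed = 99)
  cfg <- synthetic_config(
    n_subjects = n_subjects, trials_per_class = n_per_class,
    trial_seconds = 0.5, classes = 2, class_centers = c("E1", "E4"),
    class_bands = list(c(8, 12), c(20, 26)), snr_db = snr_db,
    subject_gain_sd = gain_sd, seed = seed)
  list(layout = lay, trials = generate_dataset(cfg, lay))
}

toy_model_cfg <- function() {
  danet_config(C = 5, T = 40, n_classes = 2,
               mff = mff_config(kernel_sizes = c(3, 7), depths = c(2, 2),
                                att_hidden = 4),
               gat = gat_config(n_layers = 2, heads = 2, hidden_dim = 4))
}

toy_segments <- function(trials) sliding_window(trials, window = 40,
                                                stride = 20)

test_that("adjacency updates follow the floor(epochs / period) schedule", {
  ts <- toy_synth()
  segs <- toy_segments(ts$trials)
  m <- danet_model(ts$layout, toy_model_cfg(), seed = 1)
  tc <- train_config(epochs = 7, update_period = 3, batch_size = 32,
                     seed = 1)
  m <- train(m, segs, tc)
  expect_equal(m$adj$update_count, 7L %/% 3L)
  expect_length(m$adj$history, 2)
  expect_equal(nrow(m$history), 7)
  # the published schedule: 33 updates by epoch 334 at period 10
  expect_equal(334L %/% 10L, 33L)
})

test_that("training is deterministic given the seed", {
  ts <- toy_synth()
  segs <- toy_segments(ts$trials)
  run <- function() {
    m <- danet_model(ts$layout, toy_model_cfg(), seed = 4)
    train(m, segs, train_config(epochs = 3, update_period = 2,
                                batch_size = 32, seed = 4))
  }
  a <- run(); b <- run()
  expect_equal(a$history$loss, b$history$loss, tolerance = 1e-6)
  expect_identical(a$params, b$params)
  expect_identical(a$adj$P, b$adj$P)
})

test_that("the model can memorize a single trial's segments", {
  ts <- toy_synth(n_per_class = 1, snr_db = 0)
  segs <- toy_segments(ts$trials)   # 2 trials (one per class)
  m <- danet_model(ts$layout, toy_model_cfg(), seed = 2)
  m <- train(m, segs, train_config(epochs = 60, update_period = 100,
                                   batch_size = 4, seed = 2))
  expect_equal(utils::tail(m$history$train_acc, 1), 1.0)
})

test_that("training rejects degenerate inputs", {
  ts <- toy_synth(n_per_class = 2)
  segs <- toy_segments(ts$trials)
  one_class <- segs[segs$labels == 0]
  m <- danet_model(ts$layout, toy_model_cfg(), seed = 1)
  expect_error(train(m, one_class, train_config(epochs = 1)),
               "2 classes")
})

test_that("within-subject protocol reports five repeats and their mean", {
  ts <- toy_synth(n_per_class = 8, snr_db = 15)
  tc <- train_config(epochs = 3, update_period = 2, batch_size = 32,
                     seed = 5)
  rep <- eval_within_subject(ts$trials, toy_model_cfg(), tc, ts$layout,
                             repeats = 5, window = 40, stride = 20)
  expect_s3_class(rep, "eval_report")
  expect_length(rep$per_repeat_acc, 5)
  expect_equal(rep$mean_acc, mean(rep$per_repeat_acc))
  # repeats * classes * held-out trials * segments-per-trial
  expect_equal(sum(rep$per_class_confusion), 5 * 2 * 2 * 3)
  # learnable toy problem: clearly above the 50% two-class chance
  expect_gt(rep$mean_acc, 0.6)
  # identical protocol run reproduces identically
  rep2 <- eval_within_subject(ts$trials, toy_model_cfg(), tc, ts$layout,
                              repeats = 5, window = 40, stride = 20)
  expect_identical(rep$per_repeat_acc, rep2$per_repeat_acc)
})

test_that("cross-subject protocol draws disjoint subject sets", {
  ts <- toy_synth(n_per_class = 4, n_subjects = 6, gain_sd = 0.3)
  tc <- train_config(epochs = 2, update_period = 2, batch_size = 32,
                     seed = 3)
  rep <- eval_cross_subject(ts$trials, toy_model_cfg(), tc, ts$layout,
                            n_train = 4, n_test = 2, repeats = 2,
                            window = 40, stride = 20)
  expect_length(rep$per_repeat_acc, 2)
  expect_error(
    eval_cross_subject(ts$trials, toy_model_cfg(), tc, ts$layout,
                       n_train = 20, n_test = 5, window = 40, stride = 20),
    "at least 25")
})

test_that("evaluation reports serialize to JSON", {
  rep <- dganet:::new_eval_report("within", c(0.5, 0.6), c(0.5, 0.7),
                                  matrix(1:4, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_acc, 0.55)
  expect_equal(back$protocol, "within")
})
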