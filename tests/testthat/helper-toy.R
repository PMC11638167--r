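# shared fixtures: toy layouts, tiny model configurations, and a memoized
# desk-scale trained model reused by the slower checks

toy_layout <- function(C = 5, seed = 1) {
  set.seed(seed)
  montage_layout(paste0("E", seq_len(C)), matrix(rnorm(3 * C), C))
}

tiny_config <- function(C = 3, T = 8, n_classes = 3) {
  danet_config(
    C = C, T = T, n_classes = n_classes,
    mff = mff_config(kernel_sizes = c(3, 5), depths = c(2, 2),
                     att_hidden = 4),
    gat = gat_config(n_layers = 2, heads = 2, hidden_dim = 3))
}

# training conditions for the desk-scale learning checks: full 64-channel
# geometry and segment shape, reduced trial count and epochs
desk_scale <- list(trials_per_class = 8, snr_db = 10, epochs = 12,
                   update_period = 2, seed = 7)

.fixture_env <- new.env(parent = emptyenv())

# memoized: one high-SNR synthetic subject, split, trained model
trained_fixture <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  lay <- load_builtin_montage()
  cfg <- synthetic_config(trials_per_class = desk_scale$trials_per_class,
                          snr_db = desk_scale$snr_db,
                          seed = desk_scale$seed)
  trials <- generate_dataset(cfg, lay)
  sp <- split_trials(trials, 0.8, seed = desk_scale$seed)
  seg_tr <- sliding_window(sp$train)
  seg_te <- sliding_window(sp$test)
  model <- danet_model(lay, danet_config(), seed = desk_scale$seed)
  tc <- train_config(epochs = desk_scale$epochs,
                     update_period = desk_scale$update_period,
                     seed = desk_scale$seed)
  model <- train(model, seg_tr, tc)
  .fixture_env$fit <- list(layout = lay, trials = trials, model = model,
                           seg_train = seg_tr, seg_test = seg_te)
  .fixture_env$fit
}

# nearest-centroid classifier on log band-power features, k-fold CV;
# the independent signal-recovery oracle for the synthetic generator
bandpower_oracle_cv <- function(trials, bands, folds = 5, seed = 1) {
  feat <- dganet:::bandpower_features(trials, bands)
  y <- trials$labels
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  hits <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    cents <- t(vapply(sort(unique(y)), function(cl) {
      colMeans(feat[tr & y == cl, , drop = FALSE])
    }, numeric(ncol(feat))))
    d <- as.matrix(stats::dist(rbind(feat[!tr, , drop = FALSE], cents)))
    nte <- sum(!tr)
    dd <- d[seq_len(nte), nte + seq_len(nrow(cents)), drop = FALSE]
    pred <- sort(unique(y))[max.col(-dd)]
    hits <- hits + sum(pred == y[!tr])
  }
  hits / n
}
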