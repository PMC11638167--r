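# ---- train_eval: optimization loop and evaluation protocols ----------------

#' Training configuration
#'
#' Adam with the published settings: learning rate 0.01, weight decay 1e-4
#' (the PyTorch-Adam reading of "learning rate decay"; an explicit
#' per-epoch learning-rate schedule is available via `lr_schedule`),
#' 800 epochs, and an adjacency update every 10 epochs. Desk-scale runs
#' shrink `epochs` and the dataset, never the update rule.
#'
#' @param lr Adam learning rate (default 0.01).
#' @param weight_decay L2 coefficient added to gradients (default 1e-4).
#' @param epochs Training epochs (default 800).
#' @param batch_size Segments per minibatch (default 64).
#' @param update_period Epochs between adjacency updates (default 10).
#' @param lr_schedule Optional function(epoch) -> multiplier on `lr`;
#'   NULL keeps the rate constant (the default reading).
#' @param seed Integer seed covering shuffling (and, through
#'   [danet_model()], initialization when the caller uses the same seed).
#' @param verbose Print per-epoch progress every `verbose` epochs
#'   (0 = silent).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.01, weight_decay = 1e-4, epochs = 800,
                         batch_size = 64, update_period = 10,
                         lr_schedule = NULL, seed = 1, verbose = 0) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch_size >= 1,
            update_period >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 update_period = as.integer(update_period),
                 lr_schedule = lr_schedule, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

#' Train a decoder on segments
#'
#' Minimizes cross-entropy with Adam. Layer-3 node embeddings are averaged
#' over each epoch's training samples, and every `update_period` epochs the
#' working adjacency is re-weighted from them via [update_adjacency()]
#' (so after `n` epochs, `floor(n / update_period)` updates have
#' occurred -- e.g. 33 updates by epoch 334 with the default period 10).
#' Fully deterministic given the seed under single-threaded numerics.
#'
#' @param model A [danet_model()].
#' @param segments Training `eeg_segments` (labels must cover >= 2
#'   classes).
#' @param cfg A [train_config()].
#' @param eval_segments Optional held-out `eeg_segments` scored once per
#'   epoch into the history (protocol runners use this for curves only,
#'   never for parameter selection unless explicitly requested).
#' @return The trained model, with `$history` (data frame: epoch, loss,
#'   train_acc, eval_acc) and the updated adjacency state attached.
#' @export
train <- function(model, segments, cfg = train_config(),
                  eval_segments = NULL) {
  stopifnot(inherits(model, "danet_model"),
            inherits(segments, "eeg_segments"))
  N <- n_items(segments)
  if (N == 0) stop("no training segments")
  if (length(unique(segments$labels)) < 2) {
    stop("training labels must cover at least 2 classes")
  }
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), eval_acc = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$lr * if (is.null(cfg$lr_schedule)) 1 else cfg$lr_schedule(ep)
      ord <- sample.int(N)
      ep_loss <- 0; ep_hits <- 0
      g3_sum <- matrix(0, model$config$C, model$config$gat$hidden_dim)
      for (at in seq(1, N, by = cfg$batch_size)) {
        idx <- ord[at:min(at + cfg$batch_size - 1, N)]
        Xb <- segments$data[idx, , , drop = FALSE]
        yb <- segments$labels[idx]
        fw <- danet_forward_batch(model, Xb, yb, with_cache = TRUE)
        if (!is.finite(fw$loss)) {
          stop("non-finite loss at epoch ", ep, " (lr=", lr,
               "); last grad norm ",
               tryCatch(grad_norm(danet_backward_batch(model, fw$cache, yb)),
                        error = function(e) NA))
        }
        gr <- danet_backward_batch(model, fw$cache, yb)
        st <- adam_step(model$params, gr, opt, lr, cfg$weight_decay)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + fw$loss * length(idx)
        ep_hits <- ep_hits + sum(max.col(fw$probs) - 1L == yb)
        # accumulate per-node layer-3 embedding means for the graph update
        arr <- array(fw$G3, c(model$config$C, length(idx),
                              model$config$gat$hidden_dim))
        g3_sum <- g3_sum + colSums(aperm(arr, c(2, 1, 3)))
      }
      model$g3_mean <- g3_sum / N
      if (ep %% cfg$update_period == 0) {
        model$adj <- update_adjacency(model$adj, model$g3_mean,
                                      model$config$gat)
      }
      eval_acc <- NA_real_
      if (!is.null(eval_segments)) {
        pr <- predict(model, eval_segments, cfg$batch_size)
        eval_acc <- mean(max.col(pr) - 1L == eval_segments$labels)
      }
      hist[nrow(hist) + 1L, ] <- list(ep, ep_loss / N, ep_hits / N, eval_acc)
      if (cfg$verbose > 0 && ep %% cfg$verbose == 0) {
        message(sprintf("epoch %d/%d loss %.4f acc %.3f%s", ep, cfg$epochs,
                        ep_loss / N, ep_hits / N,
                        if (is.na(eval_acc)) "" else
                          sprintf(" eval %.3f", eval_acc)))
      }
    }
  })
  model$history <- hist
  model
}

#' Segment-level accuracy of a model on segments
#' @param model A trained [danet_model()].
#' @param segments `eeg_segments` with labels.
#' @return Fraction of correctly classified segments.
#' @export
segment_accuracy <- function(model, segments) {
  pr <- predict(model, segments)
  mean(max.col(pr) - 1L == segments$labels)
}

# trial-level majority vote over a trial's segment predictions
trial_vote_accuracy <- function(model, segments) {
  pr <- predict(model, segments)
  pred <- max.col(pr) - 1L
  key <- paste(segments$subject, segments$trial)
  hits <- vapply(unique(key), function(k) {
    sel <- key == k
    vote <- as.integer(names(which.max(table(pred[sel]))))
    vote == segments$labels[sel][1]
  }, logical(1))
  mean(hits)
}

confusion_counts <- function(model, segments, n_classes) {
  pr <- predict(model, segments)
  pred <- factor(max.col(pr) - 1L, levels = 0:(n_classes - 1))
  truth <- factor(segments$labels, levels = 0:(n_classes - 1))
  unclass(table(truth, pred))
}

new_eval_report <- function(protocol, accs, vote_accs, confusion) {
  structure(list(protocol = protocol, per_repeat_acc = accs,
                 mean_acc = mean(accs),
                 per_repeat_trial_vote_acc = vote_accs,
                 per_class_confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$protocol, "-subject, ", length(x$per_repeat_acc),
      " repeats\n  segment acc: ",
      paste(sprintf("%.3f", x$per_repeat_acc), collapse = " "),
      "  mean ", sprintf("%.3f", x$mean_acc), "\n", sep = "")
  invisible(x)
}

#' Within-subject evaluation protocol
#'
#' For each of `repeats` random repetitions: split one subject's trials
#' 8:2 stratified by class (trial level, before windowing), segment both
#' sides with the sliding window, train a freshly initialized model on the
#' training segments and score segment-level accuracy on the test
#' segments. Reports every repeat's accuracy and their arithmetic mean,
#' plus a trial-level majority-vote accuracy as a clearly separate
#' convenience metric.
#'
#' @param trials `eeg_trials` of a single subject.
#' @param model_config A [danet_config()].
#' @param train_cfg A [train_config()] (its seed anchors the whole
#'   protocol; repeat r uses derived seed `seed + r`).
#' @param layout The [montage_layout()] (node order of the data rows).
#' @param ratio Training fraction of trials (default 0.8).
#' @param repeats Number of random repetitions (default 5).
#' @param window,stride Sliding-window parameters (defaults 160 / 20).
#' @return An `eval_report`.
#' @export
eval_within_subject <- function(trials, model_config = danet_config(),
                                train_cfg = train_config(),
                                layout = load_builtin_montage(),
                                ratio = 0.8, repeats = 5,
                                window = 160, stride = 20) {
  accs <- numeric(repeats); votes <- numeric(repeats)
  conf <- matrix(0L, model_config$n_classes, model_config$n_classes)
  for (r in seq_len(repeats)) {
    seed_r <- train_cfg$seed + r
    sp <- split_trials(trials, ratio, seed = seed_r)
    seg_tr <- sliding_window(sp$train, window, stride)
    seg_te <- sliding_window(sp$test, window, stride)
    model <- danet_model(layout, model_config, seed = seed_r)
    cfg_r <- train_cfg; cfg_r$seed <- seed_r
    model <- train(model, seg_tr, cfg_r)
    accs[r] <- segment_accuracy(model, seg_te)
    votes[r] <- trial_vote_accuracy(model, seg_te)
    conf <- conf + confusion_counts(model, seg_te, model_config$n_classes)
  }
  new_eval_report("within", accs, votes, conf)
}

#' Cross-subject evaluation protocol
#'
#' For each repeat, draws disjoint random subject sets (`n_train` training
#' subjects, `n_test` held-out subjects), trains on the pooled training
#' subjects' segments and scores on the pooled held-out subjects'
#' segments. Measures generalization to unseen people, which is the harder
#' setting: accuracies are expected below the matched within-subject ones.
#'
#' @param trials `eeg_trials` spanning multiple subjects.
#' @param model_config A [danet_config()].
#' @param train_cfg A [train_config()].
#' @param layout The [montage_layout()].
#' @param n_train,n_test Subjects for training / testing per repeat
#'   (defaults 20 / 5).
#' @param repeats Number of random repetitions (default 5).
#' @param window,stride Sliding-window parameters.
#' @return An `eval_report`.
#' @export
eval_cross_subject <- function(trials, model_config = danet_config(),
                               train_cfg = train_config(),
                               layout = load_builtin_montage(),
                               n_train = 20, n_test = 5, repeats = 5,
                               window = 160, stride = 20) {
  subjects <- unique(trials$subject)
  if (length(subjects) < n_train + n_test) {
    stop("need at least ", n_train + n_test, " subjects, have ",
         length(subjects))
  }
  accs <- numeric(repeats); votes <- numeric(repeats)
  conf <- matrix(0L, model_config$n_classes, model_config$n_classes)
  for (r in seq_len(repeats)) {
    seed_r <- train_cfg$seed + r
    pick <- with_seed(seed_r, sample(subjects, n_train + n_test))
    s_train <- pick[seq_len(n_train)]
    s_test <- pick[n_train + seq_len(n_test)]
    seg_tr <- sliding_window(trials[trials$subject %in% s_train],
                             window, stride)
    seg_te <- sliding_window(trials[trials$subject %in% s_test],
                             window, stride)
    model <- danet_model(layout, model_config, seed = seed_r)
    cfg_r <- train_cfg; cfg_r$seed <- seed_r
    model <- train(model, seg_tr, cfg_r)
    accs[r] <- segment_accuracy(model, seg_te)
    votes[r] <- trial_vote_accuracy(model, seg_te)
    conf <- conf + confusion_counts(model, seg_te, model_config$n_classes)
  }
  new_eval_report("cross", accs, votes, conf)
}

#' Serialize an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}
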