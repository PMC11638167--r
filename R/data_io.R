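# ---- data_io: trial containers, sliding-window segmentation, splits --------

#' Construct a trial container
#'
#' Holds N whole motor-imagery trials as an N x C x L array together with
#' per-trial metadata. Class labels are integer codes 0..(n_classes-1)
#' (0 = left fist, 1 = right fist, 2 = both fists, 3 = both feet for the
#' four-task paradigm).
#'
#' @param data Numeric array N x C x L (trials x channels x samples).
#' @param labels Integer vector of length N, class codes starting at 0.
#' @param subject Subject identifier(s), length 1 or N.
#' @param trial Unique trial identifiers, length N (default 1..N).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of length C.
#' @return Object of class `eeg_trials`.
#' @export
eeg_trials <- function(data, labels, subject = 1L, trial = NULL, fs = 160,
                       channel_names = NULL) {
  data <- as_3d(data)
  n <- dim(data)[1]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per trial")
  if (any(labels < 0)) stop("labels are 0-based non-negative codes")
  if (!all(is.finite(data))) stop("non-finite sample values in trial data")
  if (length(subject) == 1) subject <- rep(subject, n)
  if (is.null(trial)) trial <- seq_len(n)
  if (anyDuplicated(data.frame(subject, trial))) {
    stop("(subject, trial) identifiers must be unique")
  }
  structure(list(data = data, labels = labels, subject = subject,
                 trial = trial, fs = fs, channel_names = channel_names),
            class = "eeg_trials")
}

as_3d <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  if (length(dim(x)) != 3) stop("data must be an N x C x T array")
  storage.mode(x) <- "double"
  x
}

#' @export
print.eeg_trials <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_trials> ", d[1], " trials, ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz, classes: ",
      paste(names(table(x$labels)), "=", table(x$labels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of trials / segments
#' @param x An `eeg_trials` or `eeg_segments` object.
#' @return Integer count.
#' @export
n_items <- function(x) dim(x$data)[1]

#' Subset trials
#' @param x An `eeg_trials` object.
#' @param i Index vector.
#' @param ... Unused.
#' @export
`[.eeg_trials` <- function(x, i, ...) {
  eeg_trials(x$data[i, , , drop = FALSE], x$labels[i], x$subject[i],
             x$trial[i], x$fs, x$channel_names)
}

#' Concatenate trial containers
#' @param ... `eeg_trials` objects with matching channel/sample dimensions.
#' @return Combined `eeg_trials`.
#' @export
bind_trials <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "eeg_trials")) parts <- parts[[1]]
  dims <- lapply(parts, function(p) dim(p$data)[-1])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all parts must share channel and sample dimensions")
  }
  data <- do.call(abind1, lapply(parts, `[[`, "data"))
  eeg_trials(data,
             unlist(lapply(parts, `[[`, "labels")),
             unlist(lapply(parts, `[[`, "subject")),
             unlist(lapply(parts, `[[`, "trial")),
             parts[[1]]$fs, parts[[1]]$channel_names)
}

# bind 3-d arrays along the first margin
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Segment trials with a sliding window
#'
#' Cuts every trial into overlapping fixed-length windows: window `w`
#' (0-based) covers samples `[w*stride, w*stride + window)`, giving
#' `floor((L - window)/stride) + 1` segments per trial. Each segment
#' inherits its parent trial's label and provenance, which is what makes
#' trial-level splitting before windowing leak-free. A 4-s trial at 160 Hz
#' with the default window 160 / stride 20 yields 25 segments.
#'
#' @param trials An [eeg_trials()] container.
#' @param window Window length in samples (default 160).
#' @param stride Hop between window starts in samples (default 20).
#' @return Object of class `eeg_segments`: N x C x window data array plus
#'   `labels`, `subject`, `trial`, `window` (0-based window index), `fs`.
#' @export
sliding_window <- function(trials, window = 160, stride = 20) {
  stopifnot(inherits(trials, "eeg_trials"))
  L <- dim(trials$data)[3]
  window <- as.integer(window); stride <- as.integer(stride)
  if (window > L) stop("window (", window, ") exceeds trial length (", L, ")")
  if (stride < 1) stop("stride must be >= 1")
  nw <- (L - window) %/% stride + 1L
  n <- n_items(trials)
  C <- dim(trials$data)[2]
  out <- array(0, c(n * nw, C, window))
  for (w in seq_len(nw) - 1L) {
    # segments of one trial are contiguous: row (i-1)*nw + w + 1
    idx <- (seq_len(n) - 1L) * nw + w + 1L
    out[idx, , ] <- trials$data[, , w * stride + seq_len(window), drop = FALSE]
  }
  structure(list(data = out,
                 labels = rep(trials$labels, each = nw),
                 subject = rep(trials$subject, each = nw),
                 trial = rep(trials$trial, each = nw),
                 window = rep(seq_len(nw) - 1L, n),
                 fs = trials$fs,
                 channel_names = trials$channel_names),
            class = "eeg_segments")
}

#' @export
print.eeg_segments <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_segments> ", d[1], " segments (", length(unique(x$trial)),
      " trials), ", d[2], " channels x ", d[3], " samples @ ", x$fs,
      " Hz\n", sep = "")
  invisible(x)
}

#' @export
`[.eeg_segments` <- function(x, i, ...) {
  structure(list(data = x$data[i, , , drop = FALSE], labels = x$labels[i],
                 subject = x$subject[i], trial = x$trial[i],
                 window = x$window[i], fs = x$fs,
                 channel_names = x$channel_names),
            class = "eeg_segments")
}

#' Stratified trial-level train/test split
#'
#' Splits trials into train and test sets stratified by class, BEFORE any
#' windowing, so no overlapping windows of one trial can land on both sides
#' of the split. Per class, `floor(ratio * n_class)` trials go to training
#' and the remainder to test. Deterministic given `seed`.
#'
#' @param trials An [eeg_trials()] container.
#' @param ratio Training fraction, strictly inside (0, 1); default 0.8.
#' @param seed Integer seed controlling the permutation.
#' @return List with `train` and `test` [eeg_trials()].
#' @export
split_trials <- function(trials, ratio = 0.8, seed = 1) {
  stopifnot(inherits(trials, "eeg_trials"))
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be strictly inside (0, 1)")
  tab <- table(trials$labels)
  if (any(tab < 2)) {
    stop("every class needs at least 2 trials to split; counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in as.integer(names(tab))) {
      ids <- which(trials$labels == cl)
      ids <- ids[sample.int(length(ids))]
      n_tr <- floor(ratio * length(ids))
      idx_train <- c(idx_train, ids[seq_len(n_tr)])
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n_items(trials)), idx_train)
  list(train = trials[idx_train], test = trials[idx_test])
}

#' Optional 1-35 Hz zero-phase band-pass for raw recordings
#'
#' PhysioNet-style recordings are already 1-35 Hz filtered at the source,
#' so the loader does not filter by default (filtering twice would distort
#' band edges). For genuinely raw inputs this applies a 4th-order
#' Butterworth band-pass forward and backward (zero phase).
#'
#' @param trials An [eeg_trials()] container.
#' @param low,high Band edges in Hz (defaults 1 and 35).
#' @return Filtered [eeg_trials()].
#' @export
bandpass_trials <- function(trials, low = 1, high = 35) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("the 'signal' package is required for band-pass filtering")
  }
  ny <- trials$fs / 2
  bf <- signal::butter(4, c(low, high) / ny, type = "pass")
  d <- trials$data
  for (i in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      d[i, ch, ] <- signal::filtfilt(bf, d[i, ch, ])
    }
  }
  trials$data <- d
  trials
}

#' Write / read a segment or trial archive
#'
#' Single-file archive for the package's interchange objects (the R-native
#' counterpart of an array bundle: data N x C x T plus labels, subject,
#' trial, window, fs). Used by the command-line interface between stages.
#'
#' @param x An `eeg_trials` or `eeg_segments` object.
#' @param path Output file path (conventionally `.rds`).
#' @return `write_archive` returns `path` invisibly; `read_archive` the
#'   restored object.
#' @export
write_archive <- function(x, path) {
  stopifnot(inherits(x, c("eeg_trials", "eeg_segments")))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, c("eeg_trials", "eeg_segments")))
  x
}
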