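# ---- synthetic: labelled MI-EEG surrogate data with a separability dial ----

#' Configuration for the synthetic motor-imagery generator
#'
#' The generator emulates the structure a motor-imagery decoder exploits:
#' each class adds a band-limited oscillation (an event-related
#' synchronization proxy) with a class-specific scalp focus and frequency
#' band on top of 1/f-shaped background noise plus white sensor noise.
#' Cross-subject variability enters as per-channel multiplicative gains and
#' a per-subject shift of the class band centers.
#'
#' Defaults mirror the four-task 64-channel paradigm at 160 Hz with 4-s
#' trials: left fist focussed at C4 and right fist at C3 (contralateral
#' hand areas) in the mu band, both feet at the vertex CZ in the mu band,
#' and both fists at CZ in the beta band so the two midline classes are
#' spectrally distinct.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param trials_per_class Trials per class per subject (default 21, i.e.
#'   84 trials per subject for 4 classes).
#' @param fs Sampling rate in Hz (default 160).
#' @param trial_seconds Trial duration in seconds (default 4).
#' @param classes Number of classes (default 4).
#' @param class_centers Electrode label of each class's scalp focus.
#' @param class_bands 2 x classes matrix (or list) of band edges in Hz.
#' @param spatial_sigma Gaussian falloff length of the focus, in montage
#'   coordinate units (chord length on the unit sphere; default 0.4, about
#'   two electrode spacings).
#' @param snr_db Signal-to-noise ratio in dB at the focus electrode:
#'   oscillation power relative to unit background power.
#' @param subject_gain_sd SD of per-subject per-channel log-normal gains.
#' @param subject_freq_jitter_hz SD of the per-subject class-band center
#'   shift in Hz.
#' @param pink_exponent Spectral exponent of the 1/f^a background
#'   amplitude shaping (default 0.7).
#' @param white_frac Fraction of background noise power that is white
#'   sensor noise (default 0.2).
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 1, trials_per_class = 21,
                             fs = 160, trial_seconds = 4, classes = 4,
                             class_centers = c("C4", "C3", "CZ", "CZ"),
                             class_bands = list(c(8, 12), c(8, 12),
                                                c(18, 26), c(8, 12)),
                             spatial_sigma = 0.4, snr_db = 5,
                             subject_gain_sd = 0.2,
                             subject_freq_jitter_hz = 1,
                             pink_exponent = 0.7, white_frac = 0.2,
                             seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_class = as.integer(trials_per_class),
              fs = fs, trial_seconds = trial_seconds,
              classes = as.integer(classes),
              class_centers = toupper(class_centers),
              class_bands = class_bands,
              spatial_sigma = spatial_sigma, snr_db = snr_db,
              subject_gain_sd = subject_gain_sd,
              subject_freq_jitter_hz = subject_freq_jitter_hz,
              pink_exponent = pink_exponent, white_frac = white_frac,
              seed = as.integer(seed))
  stopifnot(cfg$trials_per_class >= 1, cfg$classes >= 1,
            is.finite(cfg$snr_db),
            length(cfg$class_centers) == cfg$classes,
            length(cfg$class_bands) == cfg$classes)
  for (b in cfg$class_bands) {
    if (!(b[1] > 0 && b[2] > b[1] && b[2] < fs / 2)) {
      stop("class band (", b[1], ", ", b[2], ") must lie inside (0, fs/2)")
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# 1/f^a-shaped Gaussian noise, unit variance, length n
pink_noise <- function(n, fs, a) {
  f <- seq(0, fs / 2, length.out = n %/% 2 + 1)
  shape <- c(0, 1 / f[-1]^a)                  # kill DC
  # hermitian spectrum from white gaussian half-spectrum
  half <- (stats::rnorm(length(f)) + 1i * stats::rnorm(length(f))) * shape
  half[1] <- 0
  if (n %% 2 == 0) half[length(half)] <- Re(half[length(half)])
  full <- c(half, Conj(rev(half[2:(length(half) - (n %% 2 == 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic labelled MI-EEG dataset
#'
#' See [synthetic_config()] for the signal model. Output is one
#' [eeg_trials()] container holding all subjects' trials; identical
#' configurations (including `seed`) reproduce identical arrays.
#'
#' @param cfg A [synthetic_config()].
#' @param layout A [montage_layout()]; class centers must be among its
#'   electrode labels.
#' @return An [eeg_trials()] container with
#'   `n_subjects * classes * trials_per_class` trials.
#' @export
generate_dataset <- function(cfg, layout = load_builtin_montage()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  miss <- setdiff(cfg$class_centers, layout$names)
  if (length(miss)) {
    stop("unknown center electrode(s): ", paste(miss, collapse = ", "))
  }
  C <- n_channels(layout)
  L <- round(cfg$fs * cfg$trial_seconds)
  tt <- seq_len(L) / cfg$fs
  # spatial weight of each class focus over electrodes
  W <- vapply(seq_len(cfg$classes), function(k) {
    d <- sqrt(colSums((t(layout$coords) -
                         layout$coords[cfg$class_centers[k], ])^2))
    exp(-d^2 / (2 * cfg$spatial_sigma^2))
  }, numeric(C))
  amp <- sqrt(2 * 10^(cfg$snr_db / 10))  # unit noise power at the focus
  n_per_subj <- cfg$classes * cfg$trials_per_class
  N <- cfg$n_subjects * n_per_subj
  data <- array(0, c(N, C, L))
  labels <- integer(N)
  subject <- integer(N)
  with_seed(cfg$seed, {
    i <- 0
    for (s in seq_len(cfg$n_subjects)) {
      gains <- exp(stats::rnorm(C, 0, cfg$subject_gain_sd))
      fshift <- stats::rnorm(1, 0, cfg$subject_freq_jitter_hz)
      for (k in seq_len(cfg$classes)) {
        band <- cfg$class_bands[[k]] + fshift
        band <- pmin(pmax(band, 0.5), cfg$fs / 2 - 0.5)
        for (r in seq_len(cfg$trials_per_class)) {
          i <- i + 1
          bg <- vapply(seq_len(C), function(ch) {
            sqrt(1 - cfg$white_frac) *
              pink_noise(L, cfg$fs, cfg$pink_exponent) +
              sqrt(cfg$white_frac) * stats::rnorm(L)
          }, numeric(L))                       # L x C
          fc <- stats::runif(1, band[1], band[2])
          phi <- stats::runif(1, 0, 2 * pi)
          osc <- amp * sin(2 * pi * fc * tt + phi)   # length L
          x <- t(bg) + W[, k] %o% osc               # C x L
          data[i, , ] <- x * gains
          labels[i] <- k - 1L
          subject[i] <- s
        }
      }
    }
  })
  eeg_trials(data, labels, subject, fs = cfg$fs,
             channel_names = layout$names)
}

# log band-power features: one value per channel per band (trials x C*bands)
bandpower_features <- function(trials, bands) {
  d <- trials$data
  N <- dim(d)[1]; C <- dim(d)[2]; L <- dim(d)[3]
  f <- seq(0, trials$fs / 2, length.out = L %/% 2 + 1)
  feat <- matrix(0, N, C * length(bands))
  for (i in seq_len(N)) {
    X <- t(d[i, , ])                          # L x C
    P <- abs(stats::mvfft(X))^2 / L           # periodogram
    P <- P[seq_along(f), , drop = FALSE]
    col <- 0
    for (b in bands) {
      sel <- f >= b[1] & f <= b[2]
      feat[i, col + seq_len(C)] <- log(colMeans(P[sel, , drop = FALSE]))
      col <- col + C
    }
  }
  feat
}

#' Fisher-style class separability of a dataset
#'
#' Computes log band-power features (per channel, per configured class
#' band) and returns the ratio of between-class to within-class scatter of
#' their centroids. Near 0 for indistinguishable classes; grows with the
#' generator's signal-to-noise ratio, which makes it the quantitative
#' "separability dial" the test-suite asserts on.
#'
#' @param trials An [eeg_trials()] container with at least 2 classes.
#' @param bands List of frequency bands used as features; defaults to the
#'   distinct bands of [synthetic_config()].
#' @return Scalar separability score (between / within scatter).
#' @export
class_separability <- function(trials,
                               bands = list(c(8, 12), c(18, 26))) {
  if (length(unique(trials$labels)) < 2) {
    stop("separability needs at least two classes")
  }
  feat <- bandpower_features(trials, bands)
  mu <- colMeans(feat)
  between <- 0; within <- 0
  for (cl in unique(trials$labels)) {
    Fk <- feat[trials$labels == cl, , drop = FALSE]
    mk <- colMeans(Fk)
    between <- between + nrow(Fk) * sum((mk - mu)^2)
    within <- within + sum(sweep(Fk, 2, mk)^2)
  }
  between / within
}
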