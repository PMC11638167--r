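# ---- data_io: minimal EDF/EDF+ reader and the PhysioNet trial extractor ----

read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Read an EDF / EDF+ recording
#'
#' Minimal reader for European Data Format files as used by PhysioNet-style
#' EEG archives: fixed-width ASCII header, 16-bit little-endian sample
#' records, digital-to-physical scaling per signal, and EDF+ time-stamped
#' annotation lists ("EDF Annotations" signal) parsed into an event table.
#'
#' @param path Path to the `.edf` file.
#' @return List with `signals` (named list of numeric vectors in physical
#'   units), `fs` (named vector of per-signal sampling rates in Hz),
#'   `annotations` (data frame: onset seconds, duration seconds, text),
#'   `record_duration`, `n_records`, and `labels` (signal order).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (!startsWith(version, "0")) stop("not an EDF file (version '",
                                      version, "'): ", path)
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))   # ids, date, time
  invisible(read_ascii(con, 8))                      # header byte count
  invisible(read_ascii(con, 44))                     # reserved / EDF+ flag
  n_records <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  invisible(field(80))                               # transducer
  invisible(field(8))                                # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  invisible(field(80))                               # prefiltering
  nsamp <- as.integer(field(8))
  invisible(field(32))                               # reserved
  is_annot <- labels == "EDF Annotations"
  store <- lapply(seq_len(ns), function(i) vector("list", n_records))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        store[[i]][[r]] <- readBin(con, "raw", 2L * nsamp[i])
      } else {
        store[[i]][[r]] <- readBin(con, "integer", nsamp[i], size = 2,
                                   signed = TRUE, endian = "little")
      }
    }
  }
  signals <- list()
  fs <- numeric(0)
  annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                            text = character(0))
  for (i in seq_len(ns)) {
    if (is_annot[i]) {
      annotations <- rbind(annotations,
                           parse_tal(unlist(store[[i]], use.names = FALSE)))
    } else {
      dig <- unlist(store[[i]], use.names = FALSE)
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      signals[[labels[i]]] <- (dig - dig_min[i]) * scale + phys_min[i]
      fs[labels[i]] <- nsamp[i] / rec_dur
    }
  }
  list(signals = signals, fs = fs, annotations = annotations,
       record_duration = rec_dur, n_records = n_records,
       labels = labels[!is_annot])
}

# parse EDF+ time-stamped annotation lists from the raw annotation bytes
parse_tal <- function(bytes) {
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    text = character(0))
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    head_part <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_part[1]))
    if (is.na(onset)) next
    duration <- if (length(head_part) > 1) {
      suppressWarnings(as.numeric(head_part[2]))
    } else NA_real_
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (lb in labs) {
      out[nrow(out) + 1L, ] <- list(onset, duration, lb)
    }
  }
  out
}

# PhysioNet label normalization: "Fc5." -> "FC5"
normalize_channel <- function(x) gsub("\\.+$", "", toupper(trimws(x)))

# runs with imagery tasks and their annotation -> class code maps
physionet_run_classes <- function(run) {
  if (run %in% c(4, 8, 12)) c(T1 = 0L, T2 = 1L)        # left / right fist
  else if (run %in% c(6, 10, 14)) c(T1 = 2L, T2 = 3L)  # both fists / feet
  else NULL
}

physionet_excluded_subjects <- c(88L, 89L, 92L, 100L, 104L)

#' Extract four-class imagery trials from PhysioNet-style EDF files
#'
#' Cuts 4-s trials at the T1/T2 annotation onsets of the motor-imagery
#' runs, maps them to the four-class coding (0 = left fist, 1 = right
#' fist from runs 4/8/12; 2 = both fists, 3 = both feet from runs
#' 6/10/14 -- the dataset's standard run/annotation convention), reorders
#' channels to the montage order, and drops rest periods and the
#' movement-execution runs. Subjects with known corrupted recordings
#' (88, 89, 92, 100, 104) are skipped when `exclude_damaged` is TRUE.
#'
#' @param edf_paths Character vector of file paths named like
#'   `S001R04.edf` (subject/run parsed from the name; a `runs` vector may
#'   override).
#' @param layout Target [montage_layout()]; all its channels must be
#'   present in the recording.
#' @param trial_seconds Trial length to cut (default 4).
#' @param exclude_damaged Skip the known-bad subjects (default TRUE).
#' @param runs Optional integer vector overriding the run number per path.
#' @param bandpass Apply the optional 1-35 Hz zero-phase filter for raw
#'   recordings (default FALSE: PhysioNet data are already band-limited).
#' @return An [eeg_trials()] container (possibly with 0 trials).
#' @export
load_physionet_subject <- function(edf_paths, layout = load_builtin_montage(),
                                   trial_seconds = 4, exclude_damaged = TRUE,
                                   runs = NULL, bandpass = FALSE) {
  C <- n_channels(layout)
  data_list <- list(); labels <- integer(0); subjects <- integer(0)
  for (pi in seq_along(edf_paths)) {
    path <- edf_paths[pi]
    base <- basename(path)
    subj <- as.integer(sub("^S(\\d+)R.*$", "\\1", base))
    run <- if (!is.null(runs)) runs[pi] else
      as.integer(sub("^S\\d+R(\\d+)\\..*$", "\\1", base))
    if (is.na(subj) || is.na(run)) {
      stop("cannot parse subject/run from file name: ", base)
    }
    if (exclude_damaged && subj %in% physionet_excluded_subjects) {
      message("skipping subject ", subj, " (known corrupted recordings)")
      next
    }
    cls_map <- physionet_run_classes(run)
    if (is.null(cls_map)) {
      message("skipping run ", run, " (not a four-class imagery run)")
      next
    }
    edf <- read_edf(path)
    chan <- normalize_channel(names(edf$signals))
    missing <- setdiff(layout$names, chan)
    if (length(missing)) {
      stop("recording ", base, " lacks channels: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    sel <- match(layout$names, chan)
    fs <- unname(edf$fs[sel[1]])
    if (abs(fs - 160) > 1e-9) {
      stop("expected 160 Hz sampling, found ", fs, " Hz in ", base)
    }
    L <- round(fs * trial_seconds)
    X <- do.call(rbind, lapply(edf$signals[sel], as.numeric))  # C x total
    ann <- edf$annotations
    ann <- ann[ann$text %in% names(cls_map), , drop = FALSE]
    for (k in seq_len(nrow(ann))) {
      start <- round(ann$onset[k] * fs) + 1L
      if (start + L - 1L > ncol(X)) {
        message("dropping truncated trial at ", ann$onset[k], " s in ", base)
        next
      }
      data_list[[length(data_list) + 1L]] <- X[, start:(start + L - 1L)]
      labels <- c(labels, cls_map[[ann$text[k]]])
      subjects <- c(subjects, subj)
    }
  }
  if (length(data_list) == 0) {
    return(eeg_trials(array(0, c(0, C, round(160 * trial_seconds))),
                      integer(0), integer(0), integer(0), 160,
                      layout$names))
  }
  arr <- array(0, c(length(data_list), C, ncol(data_list[[1]])))
  for (i in seq_along(data_list)) arr[i, , ] <- data_list[[i]]
  out <- eeg_trials(arr, labels, subjects, fs = 160,
                    channel_names = layout$names)
  if (bandpass) out <- bandpass_trials(out)
  out
}
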