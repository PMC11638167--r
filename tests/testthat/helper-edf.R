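# minimal EDF+ writer used to build test recordings at run time (binary
# fixtures are never stored in the repository)

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

# signals: C x L matrix (physical units); events: data.frame(onset, text)
write_edf_fixture <- function(path, signals, fs, channel_names,
                              events = NULL, record_seconds = 1) {
  C <- nrow(signals); L <- ncol(signals)
  nsamp <- as.integer(fs * record_seconds)
  n_rec <- ceiling(L / nsamp)
  total <- n_rec * nsamp
  if (total > L) {
    signals <- cbind(signals, matrix(0, C, total - L))
  }
  has_ann <- !is.null(events)
  ns <- C + as.integer(has_ann)
  ann_bytes <- 64L            # 32 two-byte samples per record
  phys_min <- -3277; phys_max <- 3276.9
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, eos = NULL)
  wr("0", 8)
  wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr(if (has_ann) "EDF+C" else "", 44)
  wr(n_rec, 8); wr(record_seconds, 8); wr(ns, 4)
  labels <- c(channel_names, if (has_ann) "EDF Annotations")
  for (lb in labels) wr(lb, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(C)) wr(nsamp, 8)
  if (has_ann) wr(ann_bytes / 2, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * nsamp + seq_len(nsamp)
    for (i in seq_len(C)) {
      dig <- round((signals[i, cols] - phys_min) * scale) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
    if (has_ann) {
      # record-keeping TAL plus any events whose onset falls in this record
      tal <- sprintf("+%g\x14\x14", (r - 1) * record_seconds)
      t0 <- (r - 1) * record_seconds; t1 <- r * record_seconds
      sel <- events$onset >= t0 & events$onset < t1
      for (k in which(sel)) {
        tal <- paste0(tal, sprintf("+%g\x14%s\x14", events$onset[k],
                                   events$text[k]))
      }
      bytes <- charToRaw(tal)
      if (length(bytes) > ann_bytes) stop("annotation record overflow")
      writeBin(c(bytes, raw(ann_bytes - length(bytes))), con)
    }
  }
  path
}
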