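#' Write signals to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, physical scaling per
#' channel, one fixed-duration data record group. Sufficient for the
#' single-channel PSG exchange contract used by this package.
#'
#' @param signals named list of equal-length numeric vectors (channel name ->
#'   signal).
#' @param fs sampling rate in Hz (shared by all channels).
#' @param path output file.
#' @param record_seconds data record duration (default 30; trailing samples
#'   that do not fill a record are dropped).
#' @param patient,recording_id free-text header fields.
#' @return invisibly, `path`.
#' @export
write_edf <- function(signals, fs, path, record_seconds = 30,
                      patient = "X", recording_id = "synthetic") {
  stopifnot(is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  ns <- length(signals)
  len <- unique(vapply(signals, length, integer(1)))
  if (length(len) != 1) stop("all channels must have equal length")
  spr <- round(fs * record_seconds)
  n_rec <- len %/% spr
  if (n_rec < 1) stop("signal shorter than one data record")

  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  header_bytes <- 256 + 256 * ns
  writeChar(paste0(
    pad("0", 8), pad(patient, 80), pad(recording_id, 80),
    pad("01.01.26", 8), pad("00.00.00", 8), pad(header_bytes, 8),
    pad("", 44), pad(n_rec, 8), pad(format(record_seconds), 8), pad(ns, 4)
  ), con, eos = NULL)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(signals[[i]])
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    # widen slightly so rounding never clips
    phys_min[i] <- rng[1] - 1e-6 * diff(rng)
    phys_max[i] <- rng[2] + 1e-6 * diff(rng)
  }
  field <- function(vals, w) paste(vapply(vals, pad, character(1), w = w), collapse = "")
  writeChar(paste0(
    field(names(signals), 16), field(rep("", ns), 80), field(rep("uV", ns), 8),
    field(formatC(phys_min, format = "g", digits = 7), 8),
    field(formatC(phys_max, format = "g", digits = 7), 8),
    field(rep(-32768, ns), 8), field(rep(32767, ns), 8),
    field(rep("", ns), 80), field(rep(spr, ns), 8), field(rep("", ns), 32)
  ), con, eos = NULL)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_rec * spr)]
    d <- (x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768
    dig[[i]] <- as.integer(round(d))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [write_edf()]; reads all channels with physical scaling.
#'
#' @param path EDF file.
#' @return list with `signals` (named list of numeric vectors), `fs` (named
#'   numeric, per channel), `record_seconds`, `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("unreadable EDF header: ", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  seek(con, header_bytes)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      x <- (d - dig_min[i]) / (dig_max[i] - dig_min[i]) *
        (phys_max[i] - phys_min[i]) + phys_min[i]
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- x
    }
  }
  names(sig) <- labels
  list(signals = sig, fs = stats::setNames(spr / rec_dur, labels),
       record_seconds = rec_dur, n_records = n_rec)
}

sidecar_path <- function(path) paste0(sub("\\.edf$", "", path), ".labels.txt")

#' Write a recording as EDF plus a stage-label sidecar
#'
#' The sidecar holds one stage label per 30-s epoch per line, encoded as
#' `W, N1, N2, N3, R`.
#'
#' @param recording an [eeg_recording()].
#' @param path EDF output path (sidecar goes to `<path minus .edf>.labels.txt`).
#' @param channel channel name in the EDF header.
#' @return invisibly, `path`.
#' @export
write_recording <- function(recording, path, channel = "EEG Fpz-Cz") {
  x <- as.numeric(t(recording$epochs))
  write_edf(stats::setNames(list(x), channel), recording$sampling_rate, path,
            record_seconds = recording$epoch_seconds,
            recording_id = recording$subject_id)
  labs <- as.character(recording$labels)
  labs[labs == "REM"] <- "R"
  writeLines(labs, sidecar_path(path))
  invisible(path)
}

#' Read one channel of a recording plus its raw labels
#'
#' @param path EDF file; per-epoch labels are looked for in the sidecar file
#'   `<path minus .edf>.labels.txt` (one label per line).
#' @param channel channel name; a missing channel is an error listing the
#'   available ones.
#' @return list with `signal`, `fs`, `raw_labels` (character, possibly empty
#'   when no sidecar exists).
#' @export
read_recording <- function(path, channel) {
  edf <- read_edf(path)
  if (!channel %in% names(edf$signals)) {
    stop(sprintf("channel '%s' not present; available channels: %s",
                 channel, paste(names(edf$signals), collapse = ", ")))
  }
  lp <- sidecar_path(path)
  raw_labels <- if (file.exists(lp)) readLines(lp) else character(0)
  list(signal = edf$signals[[channel]], fs = unname(edf$fs[channel]),
       raw_labels = raw_labels)
}

#' Resample a signal to a target rate
#'
#' Rational-ratio polyphase resampling (via the `signal` package). Output
#' length is `round(length(x) * rate_out / rate_in)`.
#'
#' @param x numeric signal.
#' @param rate_in,rate_out sampling rates in Hz (> 0).
#' @return resampled signal.
#' @export
resample_signal <- function(x, rate_in, rate_out = 100) {
  stopifnot(rate_in > 0, rate_out > 0)
  if (rate_in == rate_out) return(x)
  # reduce to coprime p/q
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  k <- g(round(rate_out), round(rate_in))
  p <- round(rate_out) / k
  q <- round(rate_in) / k
  y <- signal::resample(x, p, q)
  target_len <- round(length(x) * rate_out / rate_in)
  length(y) <- target_len # pad/trim boundary effects to the exact length
  y[is.na(y)] <- 0
  y
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`filtfilt`), the standard
#' zero-phase EEG band-pass. Default band 0.3-35 Hz.
#'
#' @param x numeric signal.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate (Hz).
#' @param order filter order (default 4).
#' @return filtered signal, same length.
#' @export
bandpass_filter <- function(x, low = 0.3, high = 35, fs = 100, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Default R&K-to-AASM label map
#'
#' Total over the R&K vocabulary plus AASM-native names: N4 merges into N3;
#' MOVEMENT and UNKNOWN are dropped.
#'
#' @return named character vector raw label -> `{W, N1, N2, N3, REM, DROP}`.
#' @export
default_label_map <- function() {
  c(WAKE = "W", W = "W", REM = "REM", R = "REM",
    N1 = "N1", N2 = "N2", N3 = "N3", N4 = "N3",
    MOVEMENT = "DROP", UNKNOWN = "DROP")
}

#' Harmonize raw stage labels to the AASM five-class vocabulary
#'
#' @param raw_labels character vector of raw annotations.
#' @param map named character map as from [default_label_map()].
#' @return list with `labels` (factor over the five stages, kept epochs only)
#'   and `keep` (logical mask over the input). Unknown raw labels are an
#'   error, never silently passed through.
#' @export
harmonize_labels <- function(raw_labels, map = default_label_map()) {
  raw_labels <- as.character(raw_labels)
  bad <- setdiff(unique(raw_labels), names(map))
  if (length(bad) > 0) {
    stop("raw label(s) outside the map's domain: ", paste(bad, collapse = ", "))
  }
  mapped <- unname(map[raw_labels])
  keep <- mapped != "DROP"
  list(labels = stage_factor(mapped[keep]), keep = keep)
}

#' Trim excessive wake margins
#'
#' Keeps the index range from 30 minutes before the first non-wake epoch to
#' 30 minutes after the last one (clipped to the recording bounds), reducing
#' the wake-stage imbalance of overnight recordings.
#'
#' @param labels stage labels (factor or character over the five stages).
#' @param margin_minutes margin each side (default 30).
#' @param epoch_seconds epoch duration (default 30, so 30 min = 60 epochs).
#' @return integer `c(first, last)` 1-based inclusive index range; the full
#'   range with a warning when no sleep is present.
#' @export
trim_wake <- function(labels, margin_minutes = 30, epoch_seconds = 30) {
  labels <- stage_factor(labels)
  n <- length(labels)
  sleep <- which(labels != "W")
  if (length(sleep) == 0) {
    warning("recording contains no sleep epochs; keeping full range")
    return(c(1L, n))
  }
  m <- round(margin_minutes * 60 / epoch_seconds)
  c(max(1L, min(sleep) - m), min(n, max(sleep) + m))
}

#' Preprocessing configuration
#'
#' @param target_rate target sampling rate (Hz).
#' @param band band-pass edges (Hz).
#' @param epoch_seconds epoch duration.
#' @param wake_trim_minutes numeric margin for wake trimming, or `NULL` to
#'   skip trimming (trimming is a per-dataset choice).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 100, band = c(0.3, 35),
                              epoch_seconds = 30, wake_trim_minutes = NULL) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_rate / 2)) {
    stop("band must satisfy 0 < low < high < target_rate/2")
  }
  structure(list(target_rate = target_rate, band = band,
                 epoch_seconds = epoch_seconds,
                 wake_trim_minutes = wake_trim_minutes),
            class = "preprocess_config")
}

#' Dataset profiles
#'
#' Named presets selecting the EEG channel and trim behavior per supported
#' dataset family. The Sleep-EDF profile keeps its native 100 Hz (no
#' resampling) and applies wake trimming; the other PSG cohorts resample to
#' 100 Hz without trimming.
#'
#' @param name one of `"sleep-edf"`, `"physio2018"`, `"shhs"`, `"synthetic"`.
#' @return list with `channel` and a `preprocess_config`.
#' @export
dataset_profile <- function(name = c("sleep-edf", "physio2018", "shhs", "synthetic")) {
  name <- match.arg(name)
  switch(name,
    "sleep-edf" = list(channel = "EEG Fpz-Cz",
                       config = preprocess_config(wake_trim_minutes = 30)),
    "physio2018" = list(channel = "C3-A2", config = preprocess_config()),
    "shhs" = list(channel = "C4-A1", config = preprocess_config()),
    "synthetic" = list(channel = "EEG Fpz-Cz", config = preprocess_config())
  )
}

#' Full preprocessing pipeline
#'
#' resample -> band-pass -> epoch -> harmonize labels -> (optional) wake
#' trim. Trailing samples not filling a whole epoch are dropped; every
#' surviving epoch has exactly `target_rate * epoch_seconds` samples and a
#' five-class label.
#'
#' @param signal numeric signal.
#' @param fs_in input sampling rate (Hz).
#' @param raw_labels one raw stage annotation per epoch.
#' @param config a [preprocess_config()].
#' @param map label map, default [default_label_map()].
#' @param subject_id identifier for the resulting recording.
#' @return an [eeg_recording()].
#' @export
preprocess_recording <- function(signal, fs_in, raw_labels,
                                 config = preprocess_config(),
                                 map = default_label_map(),
                                 subject_id = "S1") {
  x <- resample_signal(signal, fs_in, config$target_rate)
  x <- bandpass_filter(x, config$band[1], config$band[2], fs = config$target_rate)
  spe <- config$target_rate * config$epoch_seconds
  n_ep <- min(length(x) %/% spe, length(raw_labels))
  if (n_ep < 1) stop("signal shorter than one epoch")
  ep <- matrix(x[seq_len(n_ep * spe)], nrow = n_ep, byrow = TRUE)
  h <- harmonize_labels(raw_labels[seq_len(n_ep)], map)
  ep <- ep[h$keep, , drop = FALSE]
  labels <- h$labels
  if (!is.null(config$wake_trim_minutes) && length(labels) > 0) {
    rng <- trim_wake(labels, config$wake_trim_minutes, config$epoch_seconds)
    idx <- rng[1]:rng[2]
    ep <- ep[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  eeg_recording(ep, labels, sampling_rate = config$target_rate,
                epoch_seconds = config$epoch_seconds, subject_id = subject_id)
}
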