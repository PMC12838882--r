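#' Stage specification for the synthetic EEG generator
#'
#' Describes the spectral signature of one sleep stage: a set of oscillatory
#' bands with relative amplitudes, a baseline amplitude scale in microvolts,
#' and optional transient events (spindle bursts, K-complex-like
#' deflections).
#'
#' @param stage one of `W, N1, N2, N3, REM`.
#' @param oscillation_bands list of `c(low_hz, high_hz, rel_amplitude)`
#'   triplets; band edges must lie inside the 0.3-35 Hz preprocessing
#'   passband.
#' @param baseline_amplitude overall amplitude scale (microvolts, >= 0; zero
#'   yields an all-zero epoch).
#' @param transient_events optional named numeric vector of per-epoch event
#'   rates, names in `c("spindle", "kcomplex")`.
#' @param background_rel relative amplitude of the 1/f background process.
#' @return object of class `stage_spec`.
#' @export
stage_spec <- function(stage, oscillation_bands, baseline_amplitude,
                       transient_events = NULL, background_rel = 0.08) {
  stage <- match.arg(stage, SLEEP_STAGES)
  for (b in oscillation_bands) {
    if (length(b) != 3) stop("each oscillation band must be (low, high, rel_amplitude)")
    if (b[1] < 0.3 || b[2] > 35 || b[1] >= b[2]) {
      stop("band edges must satisfy 0.3 <= low < high <= 35 Hz")
    }
    if (b[3] < 0) stop("band relative amplitudes must be nonnegative")
  }
  if (baseline_amplitude < 0) stop("baseline_amplitude must be nonnegative")
  if (!is.null(transient_events)) {
    if (is.null(names(transient_events)) ||
        !all(names(transient_events) %in% c("spindle", "kcomplex"))) {
      stop("transient_events must be named rates for 'spindle' / 'kcomplex'")
    }
    if (any(transient_events < 0)) stop("event rates must be nonnegative")
  }
  structure(list(
    stage = stage,
    oscillation_bands = oscillation_bands,
    baseline_amplitude = baseline_amplitude,
    transient_events = transient_events,
    background_rel = background_rel
  ), class = "stage_spec")
}

#' Default stage specifications
#'
#' Spectral fixtures per AASM stage: posterior alpha for wake, low-amplitude
#' theta for N1, spindles and K-complexes over a theta background for N2,
#' high-amplitude delta for N3, and mixed-frequency activity with elevated
#' fast components for REM. Amplitudes decrease from N3 to the
#' low-amplitude mixed-frequency (LAMF) stages N1/REM. These are spectrally
#' controllable fixtures, not a physiological model.
#'
#' @return named list of [stage_spec()] objects, one per stage.
#' @export
default_stage_specs <- function() {
  list(
    W = stage_spec("W",
      oscillation_bands = list(c(8, 12, 1.0), c(18, 30, 0.35)),
      baseline_amplitude = 30),
    N1 = stage_spec("N1",
      oscillation_bands = list(c(4, 7, 1.0), c(8, 12, 0.40)),
      baseline_amplitude = 20),
    N2 = stage_spec("N2",
      oscillation_bands = list(c(4, 7, 1.0), c(12, 14, 0.45)),
      baseline_amplitude = 40,
      transient_events = c(spindle = 3, kcomplex = 1)),
    N3 = stage_spec("N3",
      oscillation_bands = list(c(0.5, 2, 1.0), c(4, 7, 0.15)),
      baseline_amplitude = 75),
    REM = stage_spec("REM",
      oscillation_bands = list(c(4, 8, 1.0), c(16, 30, 0.65)),
      baseline_amplitude = 20)
  )
}

#' Markov hypnogram model
#'
#' @param transition_matrix 5 x 5 row-stochastic matrix over the stages (row
#'   order W, N1, N2, N3, REM); each row must sum to 1 within 1e-12.
#' @param initial_distribution length-5 probability vector.
#' @return object of class `hypnogram_model`.
#' @export
hypnogram_model <- function(transition_matrix, initial_distribution) {
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(5L, 5L))) {
    stop("transition_matrix must be 5 x 5")
  }
  if (any(transition_matrix < 0) || any(initial_distribution < 0)) {
    stop("hypnogram model probabilities must be nonnegative")
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix rows must sum to 1 (within 1e-12)")
  }
  if (abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial_distribution must sum to 1 (within 1e-12)")
  }
  dimnames(transition_matrix) <- list(SLEEP_STAGES, SLEEP_STAGES)
  structure(list(transition_matrix = transition_matrix,
                 initial_distribution = as.numeric(initial_distribution)),
            class = "hypnogram_model")
}

#' Default sticky hypnogram chain
#'
#' A Markov chain whose stationary distribution equals the requested class
#' weights: each row keeps probability `self_transition` on its own stage and
#' distributes the remainder proportionally to the weights. High
#' self-transition mimics the persistence of real sleep stages.
#'
#' @param class_weights length-5 nonnegative vector (normalized internally);
#'   defaults to the Sleep-EDF class distribution
#'   (35.0/10.8/34.7/6.5/13.0 %).
#' @param self_transition probability of staying in the current stage on top
#'   of the weight-proportional moves (default 0.85).
#' @return a [hypnogram_model()].
#' @export
default_hypnogram_model <- function(class_weights = c(0.350, 0.108, 0.347, 0.065, 0.130),
                                    self_transition = 0.85) {
  if (length(class_weights) != 5 || any(class_weights < 0) || sum(class_weights) <= 0) {
    stop("class_weights must be 5 nonnegative values with positive sum")
  }
  w <- class_weights / sum(class_weights)
  P <- (1 - self_transition) * matrix(w, 5, 5, byrow = TRUE) +
    self_transition * diag(5)
  P <- P / rowSums(P)
  hypnogram_model(P, w)
}

#' Sample a hypnogram from a Markov model
#'
#' @param model a [hypnogram_model()].
#' @param num_epochs number of 30-s epochs (>= 1).
#' @param seed integer seed; identical seeds give identical sequences.
#' @return factor of stage labels, length `num_epochs`.
#' @export
generate_hypnogram <- function(model, num_epochs, seed) {
  stopifnot(inherits(model, "hypnogram_model"), num_epochs >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 101))
  labs <- integer(num_epochs)
  labs[1] <- sample.int(5, 1, prob = model$initial_distribution)
  if (num_epochs > 1) {
    for (k in 2:num_epochs) {
      labs[k] <- sample.int(5, 1, prob = model$transition_matrix[labs[k - 1], ])
    }
  }
  factor(SLEEP_STAGES[labs], levels = SLEEP_STAGES)
}

# save/restore the global RNG state so generators are pure in (config, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# 1/f-ish background: white noise shaped in the frequency domain
pink_noise <- function(n) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # mirror for negative frequencies
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_noise <- function(n, low, high, fs) {
  ny <- fs / 2
  bf <- signal::butter(4, c(low, high) / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

spindle_burst <- function(n, fs, at, dur = 1.0, freq = 13) {
  len <- round(dur * fs)
  idx <- at:min(n, at + len - 1)
  t <- (seq_along(idx) - 1) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx)) # Hann
  burst <- numeric(n)
  burst[idx] <- sin(2 * pi * freq * t) * w
  burst
}

kcomplex_deflection <- function(n, fs, at, dur = 1.0) {
  len <- round(dur * fs)
  idx <- at:min(n, at + len - 1)
  t <- seq(-1, 1, length.out = length(idx))
  # biphasic: derivative-of-Gaussian shape, sharp negative then positive
  shape <- -t * exp(-4 * t^2)
  shape <- shape / max(abs(shape))
  defl <- numeric(n)
  defl[idx] <- 3 * shape
  defl
}

#' Synthesize one 30-s EEG epoch
#'
#' Sums band-limited Gaussian noise per configured oscillation band (unit
#' standard deviation scaled by the band's relative amplitude), a weak 1/f
#' background, and optional transient events, then scales by the stage's
#' baseline amplitude. Purely a spectrally controlled fixture.
#'
#' @param spec a [stage_spec()].
#' @param seed integer seed.
#' @param n_samples samples per epoch (default 3000 = 30 s at 100 Hz).
#' @param fs sampling rate in Hz (default 100).
#' @return numeric vector of length `n_samples` (microvolts).
#' @export
synthesize_epoch <- function(spec, seed, n_samples = 3000, fs = 100) {
  stopifnot(inherits(spec, "stage_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 202))
  if (spec$baseline_amplitude == 0) return(numeric(n_samples))
  x <- spec$background_rel * pink_noise(n_samples)
  for (b in spec$oscillation_bands) {
    if (b[3] > 0) x <- x + b[3] * band_noise(n_samples, b[1], b[2], fs)
  }
  ev <- spec$transient_events
  if (!is.null(ev)) {
    if (!is.na(ev["spindle"]) && ev["spindle"] > 0) {
      k <- stats::rpois(1, ev["spindle"])
      if (k > 0) {
        for (at in sample.int(max(1, n_samples - fs), k)) {
          x <- x + 1.2 * spindle_burst(n_samples, fs, at)
        }
      }
    }
    if (!is.na(ev["kcomplex"]) && ev["kcomplex"] > 0) {
      k <- stats::rpois(1, ev["kcomplex"])
      if (k > 0) {
        for (at in sample.int(max(1, n_samples - fs), k)) {
          x <- x + kcomplex_deflection(n_samples, fs, at)
        }
      }
    }
  }
  spec$baseline_amplitude * x
}

#' Epoched single-channel EEG recording
#'
#' @param epochs numeric matrix, one row per 30-s epoch (3000 samples at
#'   100 Hz by default).
#' @param labels per-epoch stage labels (coerced with [stage_factor()]).
#' @param sampling_rate Hz.
#' @param epoch_seconds seconds per epoch.
#' @param subject_id identifier string.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(epochs, labels, sampling_rate = 100,
                          epoch_seconds = 30, subject_id = "S1") {
  epochs <- as.matrix(epochs)
  labels <- stage_factor(labels)
  if (nrow(epochs) != length(labels)) {
    stop("number of epochs and labels differ")
  }
  if (ncol(epochs) != sampling_rate * epoch_seconds) {
    stop("each epoch must have sampling_rate * epoch_seconds samples")
  }
  structure(list(epochs = epochs, labels = labels,
                 sampling_rate = sampling_rate,
                 epoch_seconds = epoch_seconds,
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d epochs of %d s at %g Hz\n",
              x$subject_id, nrow(x$epochs), x$epoch_seconds, x$sampling_rate))
  print(table(x$labels))
  invisible(x)
}

#' Generate a seeded synthetic dataset
#'
#' One [eeg_recording()] per subject: a hypnogram sampled from the Markov
#' model, each epoch synthesized from its stage's [stage_spec()], and the
#' whole recording z-scored so downstream augmentation noise is in normalized
#' units.
#'
#' @param n_subjects,epochs_per_subject counts (>= 1).
#' @param class_weights either a length-5 simplex vector (turned into the
#'   default sticky chain) or a [hypnogram_model()].
#' @param seed integer master seed.
#' @param specs stage specifications, default [default_stage_specs()].
#' @param normalize z-score each recording (default TRUE).
#' @return list of [eeg_recording()] objects.
#' @export
generate_dataset <- function(n_subjects, epochs_per_subject,
                             class_weights = c(0.350, 0.108, 0.347, 0.065, 0.130),
                             seed = 1, specs = default_stage_specs(),
                             normalize = TRUE) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1)
  model <- if (inherits(class_weights, "hypnogram_model")) class_weights
           else default_hypnogram_model(class_weights)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- substream_seed(seed, 1000 * s)
    labs <- generate_hypnogram(model, epochs_per_subject, sseed)
    ep <- matrix(0, epochs_per_subject, 3000)
    for (k in seq_len(epochs_per_subject)) {
      ep[k, ] <- synthesize_epoch(specs[[as.character(labs[k])]],
                                  substream_seed(sseed, k))
    }
    if (normalize) {
      mu <- mean(ep)
      sdv <- stats::sd(as.numeric(ep))
      if (sdv > 0) ep <- (ep - mu) / sdv
    }
    eeg_recording(ep, labs, subject_id = sprintf("SYN%03d", s))
  })
}

#' Sliding L-epoch sequence windows
#'
#' Builds the model inputs: windows of `L` consecutive epochs with stride one
#' epoch; each window is labeled with the stage of its last (target) epoch.
#'
#' @param recording an [eeg_recording()].
#' @param L number of consecutive epochs per window (>= 1).
#' @return object of class `eeg_sequences`: list with `X` (matrix, one row
#'   per window of `3000 * L` samples), `labels` (target-epoch stages), `L`.
#'   If the recording has fewer than `L` epochs, an empty result with a
#'   warning.
#' @export
make_sequences <- function(recording, L) {
  stopifnot(inherits(recording, "eeg_recording"), L >= 1)
  n <- nrow(recording$epochs)
  d <- ncol(recording$epochs)
  if (L > n) {
    warning(sprintf("recording has %d epochs, fewer than L = %d; empty result", n, L))
    return(structure(list(X = matrix(0, 0, d * L),
                          labels = stage_factor(character(0)), L = L),
                     class = "eeg_sequences"))
  }
  n_seq <- n - L + 1
  X <- matrix(0, n_seq, d * L)
  for (s in seq_len(n_seq)) {
    X[s, ] <- as.numeric(t(recording$epochs[s:(s + L - 1), , drop = FALSE]))
  }
  structure(list(X = X, labels = recording$labels[seq(L, n)], L = L),
            class = "eeg_sequences")
}

#' Concatenate sequence sets from several recordings
#'
#' @param recordings list of [eeg_recording()].
#' @param L window length in epochs.
#' @return one `eeg_sequences` object.
#' @export
make_sequences_all <- function(recordings, L) {
  parts <- lapply(recordings, make_sequences, L = L)
  parts <- Filter(function(p) nrow(p$X) > 0, parts)
  if (length(parts) == 0) stop("no recording long enough for L")
  structure(list(
    X = do.call(rbind, lapply(parts, `[[`, "X")),
    labels = stage_factor(unlist(lapply(parts, function(p) as.character(p$labels)))),
    L = L
  ), class = "eeg_sequences")
}

#' Band powers of an EEG segment
#'
#' Periodogram power summed over the canonical EEG bands delta (0.5-4),
#' theta (4-8), alpha (8-12), sigma (12-16) and beta (16-30) Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @return named numeric vector of 5 band powers.
#' @export
band_powers <- function(x, fs = 100) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  sp <- sp[half]; freq <- freq[half]
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                sigma = c(12, 16), beta = c(16, 30))
  vapply(bands, function(b) sum(sp[freq >= b[1] & freq < b[2]]), numeric(1))
}
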