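#' Augmentation configuration
#'
#' The six-transform stochastic pipeline used to build contrastive views:
#' amplitude shift, amplitude scaling, time shift, zero-masking, band-stop
#' filtering and additive Gaussian noise, each applied independently with a
#' fixed probability. Ranges follow the standard EEG contrastive pipeline;
#' noise sigma is in units of the (z-scored) signal's standard deviation.
#'
#' @param amplitude_shift additive shift range (microvolts / normalized units).
#' @param amplitude_scale multiplicative scale range.
#' @param time_shift shift range in samples (zero-padded, never wrapped).
#' @param zero_mask_len zero-mask length range in samples.
#' @param bandstop_low lower cutoff range (Hz) of the 2-Hz-wide stop band.
#' @param bandstop_width stop band width (Hz).
#' @param noise_sigma additive Gaussian noise sigma range.
#' @param per_transform_probability application probability per transform.
#' @param fs sampling rate assumed by the band-stop filter (Hz).
#' @return list of class `augment_config`.
#' @export
augment_config <- function(amplitude_shift = c(-10, 10),
                           amplitude_scale = c(0.5, 2),
                           time_shift = c(-300, 300),
                           zero_mask_len = c(0, 300),
                           bandstop_low = c(0.5, 30),
                           bandstop_width = 2,
                           noise_sigma = c(0, 0.2),
                           per_transform_probability = 0.5,
                           fs = 100) {
  ranges <- list(amplitude_shift = amplitude_shift, amplitude_scale = amplitude_scale,
                 time_shift = time_shift, zero_mask_len = zero_mask_len,
                 bandstop_low = bandstop_low, noise_sigma = noise_sigma)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("range ", nm, " must satisfy min <= max")
  }
  if (per_transform_probability < 0 || per_transform_probability > 1) {
    stop("per_transform_probability must lie in [0, 1]")
  }
  structure(c(ranges, list(bandstop_width = bandstop_width,
                           per_transform_probability = per_transform_probability,
                           fs = fs)),
            class = "augment_config")
}

#' Transform identifiers, in pipeline order
#' @export
AUGMENT_TRANSFORMS <- c("amplitude_shift", "amplitude_scale", "time_shift",
                        "zero_mask", "band_stop", "gaussian_noise")

#' Apply one augmentation transform
#'
#' @param x numeric signal (length >= 1).
#' @param which transform id, one of [AUGMENT_TRANSFORMS].
#' @param params optional explicit parameters (named list); when missing they
#'   are drawn uniformly from the configured ranges.
#' @param config an [augment_config()].
#' @param seed integer seed used when parameters are drawn.
#' @return transformed signal, same length as the input.
#' @export
apply_transform <- function(x, which, params = NULL,
                            config = augment_config(), seed = 1) {
  if (!which %in% AUGMENT_TRANSFORMS) stop("unknown transform id: ", which)
  n <- length(x)
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, match(which, AUGMENT_TRANSFORMS)))
  draw <- function(r) stats::runif(1, r[1], r[2])
  switch(which,
    amplitude_shift = {
      s <- if (!is.null(params$shift)) params$shift else draw(config$amplitude_shift)
      x + s
    },
    amplitude_scale = {
      s <- if (!is.null(params$scale)) params$scale else draw(config$amplitude_scale)
      x * s
    },
    time_shift = {
      k <- if (!is.null(params$shift)) params$shift else round(draw(config$time_shift))
      shift_signal(x, k)
    },
    zero_mask = {
      len <- if (!is.null(params$length)) params$length
             else round(draw(config$zero_mask_len))
      len <- min(max(len, 0), n)
      if (len == 0) return(x)
      start <- if (!is.null(params$start)) params$start
               else sample.int(n - len + 1, 1)
      x[start:(start + len - 1)] <- 0
      x
    },
    band_stop = {
      if (config$bandstop_width <= 0) return(x) # disabled
      low <- if (!is.null(params$low)) params$low else draw(config$bandstop_low)
      high <- low + config$bandstop_width
      ny <- config$fs / 2
      high <- min(high, ny * 0.999)
      bf <- signal::butter(4, c(low, high) / ny, type = "stop")
      as.numeric(signal::filtfilt(bf, x))
    },
    gaussian_noise = {
      s <- if (!is.null(params$sigma)) params$sigma else draw(config$noise_sigma)
      x + stats::rnorm(n, 0, s)
    }
  )
}

# shift with zero padding; positive k delays the signal
shift_signal <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  if (k >= n || k <= -n) return(y)
  if (k >= 0) y[(k + 1):n] <- x[1:(n - k)]
  else y[1:(n + k)] <- x[(1 - k):n]
  y
}

#' Stochastic augmentation pipeline
#'
#' Applies the six transforms in fixed order, each independently with the
#' configured probability. Each transform draws from its own seeded
#' substream, so enabling or disabling one transform does not perturb the
#' draws of the others.
#'
#' @param x numeric signal (a full L-epoch sequence).
#' @param config an [augment_config()].
#' @param seed integer seed.
#' @return augmented signal, same length; attribute `"applied"` records
#'   which transforms fired.
#' @export
augment_pipeline <- function(x, config = augment_config(), seed = 1) {
  applied <- stats::setNames(logical(6), AUGMENT_TRANSFORMS)
  for (j in seq_along(AUGMENT_TRANSFORMS)) {
    tseed <- substream_seed(seed, 7000 + j)
    old <- .Random.seed_save()
    set.seed(tseed)
    fire <- stats::runif(1) < config$per_transform_probability
    .Random.seed_restore(old)
    if (fire) {
      applied[j] <- TRUE
      x <- apply_transform(x, AUGMENT_TRANSFORMS[j], config = config,
                           seed = substream_seed(tseed, 13))
    }
  }
  attr(x, "applied") <- applied
  x
}

#' Build a multiview batch of two augmented views per sequence
#'
#' For each input sequence, two independently augmented views are produced.
#' The output stacks the first views of all sequences, then the second views,
#' with labels duplicated accordingly.
#'
#' @param sequences an `eeg_sequences` object (see [make_sequences()]).
#' @param config an [augment_config()].
#' @param seed integer seed.
#' @return list with `X` (matrix of `2 * N_b` view rows) and `labels`
#'   (length `2 * N_b`).
#' @export
make_two_views <- function(sequences, config = augment_config(), seed = 1) {
  nb <- nrow(sequences$X)
  if (nb < 1) stop("empty batch")
  V <- matrix(0, 2 * nb, ncol(sequences$X))
  for (b in seq_len(nb)) {
    V[b, ] <- augment_pipeline(sequences$X[b, ], config,
                               seed = substream_seed(seed, 2 * b))
    V[nb + b, ] <- augment_pipeline(sequences$X[b, ], config,
                                    seed = substream_seed(seed, 2 * b + 1))
  }
  list(X = V, labels = rep(sequences$labels, 2))
}
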