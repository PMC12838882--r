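test_that("hypnogram sampling respects the chain and the seed", {
  # absorbing chain: identity transitions, all initial mass on N2
  m <- hypnogram_model(diag(5), c(0, 0, 1, 0, 0))
  labs <- generate_hypnogram(m, 10, seed = 1)
  expect_equal(as.character(labs), rep("N2", 10))

  m2 <- default_hypnogram_model()
  expect_identical(generate_hypnogram(m2, 50, seed = 9),
                   generate_hypnogram(m2, 50, seed = 9))
  expect_false(identical(generate_hypnogram(m2, 50, seed = 9),
                         generate_hypnogram(m2, 50, seed = 10)))

  # law of large numbers under the uniform chain
  mu <- hypnogram_model(matrix(0.2, 5, 5), rep(0.2, 5))
  labs <- generate_hypnogram(mu, 50000, seed = 4)
  freqs <- as.numeric(table(labs) / 50000)
  expect_true(all(abs(freqs - 0.2) < 0.01))

  bad <- matrix(0.3, 5, 5)
  expect_error(hypnogram_model(bad, rep(0.2, 5)), "sum to 1")
})

test_that("synthesized epochs have the intended spectral content", {
  specs <- default_stage_specs()
  x <- synthesize_epoch(specs$N3, seed = 5)
  expect_length(x, 3000)
  pg <- stats::spec.pgram(stats::ts(x, frequency = 100), spans = 15, plot = FALSE)
  peak <- pg$freq[which.max(pg$spec)]
  expect_gte(peak, 0.5)
  expect_lte(peak, 2)

  # wake alpha peak
  xw <- synthesize_epoch(specs$W, seed = 5)
  pgw <- stats::spec.pgram(stats::ts(xw, frequency = 100), spans = 15, plot = FALSE)
  peakw <- pgw$freq[which.max(pgw$spec)]
  expect_gte(peakw, 8)
  expect_lte(peakw, 12)

  zero <- stage_spec("W", list(c(8, 12, 1)), baseline_amplitude = 0)
  expect_equal(synthesize_epoch(zero, seed = 1), numeric(3000))

  expect_identical(synthesize_epoch(specs$N2, seed = 3),
                   synthesize_epoch(specs$N2, seed = 3))
})

test_that("stage_spec validates band edges and amplitudes", {
  expect_error(stage_spec("W", list(c(0.1, 12, 1)), 30), "0.3")
  expect_error(stage_spec("W", list(c(8, 40, 1)), 30), "35")
  expect_error(stage_spec("W", list(c(8, 12, 1)), -1), "nonnegative")
})

test_that("generated datasets are reproducible with near-target class balance", {
  recs <- small_dataset()
  expect_length(recs, 4)
  expect_s3_class(recs[[1]], "eeg_recording")
  recs2 <- generate_dataset(4, 40, seed = 77)
  expect_identical(recs[[2]]$epochs, recs2[[2]]$epochs)
  expect_identical(recs[[2]]$labels, recs2[[2]]$labels)

  recs3 <- generate_dataset(1, 20, seed = 78)
  expect_false(identical(recs[[1]]$epochs[1:20, ], recs3[[1]]$epochs))

  one <- generate_dataset(1, 1, seed = 5)
  expect_equal(nrow(one[[1]]$epochs), 1)
  expect_length(one[[1]]$labels, 1)

  expect_error(generate_dataset(1, 10, class_weights = rep(0, 5)),
               "positive sum")
})

test_that("large-sample class proportions track the Sleep-EDF target weights", {
  # one long subject keeps the Markov chain mixing across all epochs
  labs <- generate_hypnogram(default_hypnogram_model(), 20000, seed = 123)
  w_frac <- mean(labs == "W")
  expect_gte(w_frac, 0.32)
  expect_lte(w_frac, 0.38)
  tab <- as.numeric(table(labs)) / 20000
  expect_true(all(abs(tab - c(0.350, 0.108, 0.347, 0.065, 0.130)) < 0.03))
})

test_that("band-power nearest-centroid separates the default stages", {
  recs <- small_dataset()
  feats <- do.call(rbind, lapply(recs, function(r) {
    t(apply(r$epochs, 1, function(e) log(band_powers(e) + 1e-12)))
  }))
  y <- factor(unlist(lapply(recs, function(r) as.character(r$labels))),
              levels = SLEEP_STAGES)
  train <- seq_len(nrow(feats)) %% 2 == 0
  centroids <- sapply(SLEEP_STAGES, function(s) {
    colMeans(feats[train & y == s, , drop = FALSE])
  })
  pred <- SLEEP_STAGES[apply(feats[!train, ], 1, function(f) {
    which.min(colSums((centroids - f)^2))
  })]
  expect_gt(mean(pred == as.character(y[!train])), 0.9)
})

test_that("sequence windowing slides by one epoch and labels the target epoch", {
  rec <- small_dataset()[[1]]
  n <- nrow(rec$epochs)

  s10 <- make_sequences(rec, 10)
  expect_equal(nrow(s10$X), n - 10 + 1)
  expect_equal(ncol(s10$X), 30000)
  expect_equal(as.character(s10$labels), as.character(rec$labels[10:n]))

  s1 <- make_sequences(rec, 1)
  expect_equal(nrow(s1$X), n)
  expect_identical(s1$labels, rec$labels)

  exact <- eeg_recording(rec$epochs[1:10, ], rec$labels[1:10])
  se <- make_sequences(exact, 10)
  expect_equal(nrow(se$X), 1)
  expect_equal(ncol(se$X), 30000)

  expect_warning(out <- make_sequences(exact, 11), "fewer than L")
  expect_equal(nrow(out$X), 0)

  # shuffling epochs permutes labels identically (L = 1)
  set.seed(1)
  perm <- sample(n)
  shuffled <- eeg_recording(rec$epochs[perm, ], rec$labels[perm])
  sperm <- make_sequences(shuffled, 1)
  expect_identical(sperm$labels, s1$labels[perm])
  expect_identical(sperm$X, s1$X[perm, ])
})
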