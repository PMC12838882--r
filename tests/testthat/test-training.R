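test_that("the early stopper counts consecutive non-improvements exactly", {
  es <- make_early_stopper(patience = 2)
  r1 <- early_stopper_update(es, 1.0)
  expect_true(r1$improved); expect_false(r1$stop)
  r2 <- early_stopper_update(es, 0.9)
  expect_true(r2$improved)
  r3 <- early_stopper_update(es, 0.95)
  expect_false(r3$improved); expect_false(r3$stop)
  r4 <- early_stopper_update(es, 0.95)
  expect_true(r4$stop)
  expect_equal(es$best, 0.9)

  # strictly decreasing losses never stop
  es2 <- make_early_stopper(patience = 3)
  stops <- vapply(seq(1, 0.1, by = -0.05), function(l) {
    early_stopper_update(es2, l)$stop
  }, logical(1))
  expect_false(any(stops))

  # patience 20 with 20 flat evaluations stops on the 20th
  es3 <- make_early_stopper(patience = 20)
  early_stopper_update(es3, 1)
  res <- vapply(1:20, function(i) early_stopper_update(es3, 1)$stop, logical(1))
  expect_false(any(res[1:19]))
  expect_true(res[20])
})

test_that("cross-entropy has its limits and multi-scale additivity", {
  ms <- asNamespace("maxsleep")
  # margin -> infinity drives the loss to zero
  losses <- vapply(c(1, 5, 20, 50), function(m) {
    ms$ce_loss_grad(list(c(0, m, 0, 0, 0)), 2)$loss
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[4], 1e-10)
  # three identical scales: exactly 3x the single-scale loss
  o <- rnorm(5)
  expect_equal(ms$ce_loss_grad(list(o, o, o), 4)$loss,
               3 * ms$ce_loss_grad(list(o), 4)$loss)
})

test_that("contrastive pre-training lowers validation loss and spares AS2C", {
  recs <- small_dataset()
  seqs <- make_sequences_all(recs, 1)
  sp <- split_sequences(seqs, 0.25, seed = 5)
  m <- tiny_model(seed = 5, d_f = 8, layers = 1, mode = "single")
  tc <- train_config(lr = 1e-3, scl_batch = 16, scl_validation_interval = 5,
                     patience = 3, max_iterations = 25)
  aug <- augment_config()

  ms <- asNamespace("maxsleep")
  val_views <- make_two_views(
    structure(list(X = sp$val$X[1:16, ], labels = sp$val$labels[1:16], L = 1),
              class = "eeg_sequences"), aug,
    seed = maxsleep:::substream_seed(5, 999331))
  loss_before <- ms$scl_eval_loss(m, val_views, 0.07)
  pre <- pretrain_scl(m, sp$train, sp$val, tc, aug, seed = 5)
  loss_after <- attr(pre, "best_val")
  expect_lt(loss_after, loss_before)

  # the classifier is untouched by phase 1
  expect_identical(pre$params$as2c, m$params$as2c)

  # history records evaluations at the configured interval
  hist <- attr(pre, "history")
  expect_true(all(hist$iteration %% 5 == 0))
})

test_that("frozen fine-tuning leaves encoder parameters bitwise unchanged", {
  recs <- small_dataset()
  seqs <- make_sequences_all(recs, 1)
  sp <- split_sequences(seqs, 0.25, seed = 6)
  m <- tiny_model(seed = 6, d_f = 8, layers = 1, mode = "single")
  tc <- train_config(lr = 1e-2, ce_batch = 32, ce_validation_interval = 5,
                     patience = 3, max_iterations = 40, freeze_encoder = TRUE)
  fin <- finetune(m, sp$train, sp$val, tc, seed = 6)
  expect_identical(fin$params$fe, m$params$fe)
  expect_identical(fin$params$shared, m$params$shared)
  expect_identical(fin$params$tse, m$params$tse)
  expect_false(identical(fin$params$as2c, m$params$as2c))

  # full fine-tuning moves the encoder
  tc2 <- train_config(lr = 1e-3, ce_batch = 16, ce_validation_interval = 5,
                      patience = 2, max_iterations = 10, freeze_encoder = FALSE)
  full <- finetune(m, sp$train, sp$val, tc2, seed = 6)
  expect_false(identical(full$params$tse, m$params$tse))
})

test_that("evaluation of a random model on balanced data sits at chance", {
  balanced <- default_hypnogram_model(rep(0.2, 5), self_transition = 0.2)
  recs <- generate_dataset(2, 500, class_weights = balanced, seed = 31)
  seqs <- make_sequences_all(recs, 1)
  m <- tiny_model(seed = 31, d_f = 8, layers = 1, mode = "single")
  rep1 <- evaluate_model(m, seqs)
  expect_equal(rep1$n, 1000)
  expect_lt(abs(rep1$accuracy - 0.2), 0.05)
  # deterministic for fixed model and data
  rep2 <- evaluate_model(m, seqs)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_equal(rownames(rep1$confusion), SLEEP_STAGES)

  # a perfect oracle scores perfectly
  perfect <- metrics_report(seqs$labels, seqs$labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
})

test_that("checkpoints round-trip and refuse incompatible configurations", {
  m <- tiny_model(seed = 7, d_f = 8, layers = 1, mode = "single")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, meta = list(phase = "scl"))
  m2 <- load_checkpoint(path, expect_config = m$config)
  expect_identical(m2$params, m$params)
  expect_equal(attr(m2, "meta")$phase, "scl")

  other <- tiny_model(seed = 7, d_f = 8, layers = 2, mode = "single")
  expect_error(load_checkpoint(path, expect_config = other$config),
               "fingerprint")
  expect_error(load_checkpoint(tempfile()), "not found")
  unlink(path)
})

test_that("stratified splitting keeps all present classes in both parts", {
  recs <- small_dataset()
  seqs <- make_sequences_all(recs, 1)
  sp <- split_sequences(seqs, 0.25, seed = 8)
  expect_equal(nrow(sp$train$X) + nrow(sp$val$X), nrow(seqs$X))
  present <- names(which(table(seqs$labels) >= 4))
  expect_true(all(present %in% as.character(unique(sp$val$labels))))
  expect_true(all(present %in% as.character(unique(sp$train$labels))))
})
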