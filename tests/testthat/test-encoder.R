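test_that("hop-indexed positional encoding reduces to the classic form at i = 3", {
  d <- 16; T <- 40
  P3 <- positional_encoding(3, T, d, R = 5)
  # classic sinusoidal encoding computed directly
  classic <- matrix(0, d, T)
  for (t in 0:(T - 1)) {
    for (j in 0:(d - 1)) {
      ang <- t / 10000^(2 * (j %/% 2) / d)
      classic[j + 1, t + 1] <- if (j %% 2 == 0) sin(ang) else cos(ang)
    }
  }
  expect_equal(P3, classic, tolerance = 1e-12)
  # t = 0: sin rows are 0, cos rows are 1
  expect_equal(P3[seq(1, d, 2), 1], rep(0, d / 2))
  expect_equal(P3[seq(2, d, 2), 1], rep(1, d / 2))

  # scale 4 hops by R = 5 with offset floor(5/2) = 2: position 5t + 2
  P4 <- positional_encoding(4, 10, d, R = 5)
  P3long <- positional_encoding(3, 60, d, R = 5)
  expect_equal(P4[, 8], P3long[, 38]) # t = 7 -> absolute position 37 (0-based)
  for (t in 0:9) expect_equal(P4[, t + 1], P3long[, 5 * t + 2 + 1])

  expect_error(positional_encoding(2, 10, d), "i >= 3")
})

test_that("positional addition is an elementwise sum with shape checking", {
  Z <- matrix(rnorm(128 * 48), 128, 48)
  P <- positional_encoding(5, 48, 128)
  expect_equal(add_positional(Z, matrix(0, 128, 48)), Z)
  expect_equal(add_positional(Z, P) - P, Z)
  expect_equal(dim(add_positional(Z, P)), c(128, 48))
  expect_error(add_positional(Z, P[, 1:10]), "shape mismatch")
})

test_that("token pooling maps window maxima with a ragged tail", {
  Z <- matrix(rnorm(4 * 1200), 4, 1200)
  expect_equal(ncol(pool_tokens(Z, 48, "max")), 25)
  expect_identical(pool_tokens(Z, 1, "max"), Z)
  v <- matrix(c(3, 1, 4, 1, 5, 9), 1)
  expect_equal(as.numeric(pool_tokens(v, 2, "max")), c(3, 4, 9))
  expect_equal(as.numeric(pool_tokens(v, 2, "avg")), c(2, 2.5, 7))
  # ragged tail: 6 values, n = 4 -> windows of 4 and 2
  expect_equal(as.numeric(pool_tokens(v, 4, "max")), c(4, 9))
  expect_equal(as.numeric(pool_tokens(v, 4, "avg")), c(9 / 4, 7))
})

test_that("strided attention matches standard attention at n = 1 and a loop oracle at n > 1", {
  cfg1 <- encoder_config(num_layers = 1, d_f = 8, heads = 2, pool_mode = "max",
                         pool_stride = 1, dropout = 0)
  w <- init_encoder_layer(cfg1, seed = 5)
  set.seed(6)
  Z <- matrix(rnorm(8 * 16), 8, 16)

  # n = 1: equivalence with full self-attention (oracle pools nothing)
  out1 <- strided_multihead_attention(Z, w, cfg1)
  expect_lt(max(abs(out1 - oracle_strided_attention(Z, Z, w, 2))), 1e-5)

  # n = 2: against the literal nested-loop oracle on the pooled keys/values
  cfg2 <- encoder_config(num_layers = 1, d_f = 8, heads = 2, pool_mode = "max",
                         pool_stride = 2, dropout = 0)
  out2 <- strided_multihead_attention(Z, w, cfg2)
  A <- pool_tokens(Z, 2, "max")
  expect_lt(max(abs(out2 - oracle_strided_attention(Z, A, w, 2))), 1e-6)

  # larger random case, 64 tokens, n = 4
  set.seed(7)
  Z64 <- matrix(rnorm(8 * 64), 8, 64)
  cfg4 <- encoder_config(num_layers = 1, d_f = 8, heads = 2, pool_mode = "max",
                         pool_stride = 4, dropout = 0)
  expect_lt(max(abs(strided_multihead_attention(Z64, w, cfg4) -
                    oracle_strided_attention(Z64, pool_tokens(Z64, 4, "max"), w, 2))),
            1e-6)

  # single token: softmax weight is exactly 1
  z1 <- matrix(rnorm(8), 8, 1)
  expect_equal(strided_multihead_attention(z1, w, cfg1),
               w$Wo %*% (w$Wv %*% z1 + w$bv) + w$bo, tolerance = 1e-10)
})

test_that("attention softmax rows are normalized and permutation-symmetric", {
  cfg <- encoder_config(num_layers = 1, d_f = 8, heads = 2, pool_mode = "max",
                        pool_stride = 3, dropout = 0)
  w <- init_encoder_layer(cfg, seed = 8)
  set.seed(9)
  Z <- matrix(rnorm(8 * 18), 8, 18)
  att <- maxsleep:::attention_fwd(Z, w, cfg)
  for (hd in att$cache$heads) {
    expect_true(all(abs(rowSums(hd$P) - 1) < 1e-6))
  }

  # permuting pooled positions together with score columns leaves output
  # unchanged: attention over K/V columns is order-free
  A <- pool_tokens(Z, 3, "max")
  perm <- sample(ncol(A))
  out_ref <- oracle_strided_attention(Z, A, w, 2)
  out_perm <- oracle_strided_attention(Z, A[, perm], w, 2)
  expect_lt(max(abs(out_ref - out_perm)), 1e-10)
})

test_that("attention multiply count strictly decreases with the pooling stride", {
  w <- init_encoder_layer(encoder_config(num_layers = 1, d_f = 16, heads = 2,
                                         pool_stride = 1, dropout = 0), seed = 1)
  set.seed(2)
  Z <- matrix(rnorm(16 * 64), 16, 64)
  counts <- vapply(c(1, 2, 4, 8), function(n) {
    cfg <- encoder_config(num_layers = 1, d_f = 16, heads = 2,
                          pool_mode = "max", pool_stride = n, dropout = 0)
    empirical_multiply_count(Z, w, cfg)$count
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("encoder layers preserve shape and act as identity with zeroed outputs", {
  cfg <- encoder_config(num_layers = 6, d_f = 8, heads = 2, pool_stride = 3,
                        dropout = 0)
  weights <- init_encoder(cfg, seed = 10)
  for (T in c(48, 240)) {
    Z <- matrix(rnorm(8 * T), 8, T)
    for (l in seq_along(weights)) Z <- encoder_layer(Z, weights[[l]], cfg)
    expect_equal(dim(Z), c(8, T))
  }

  # zero attention output-projection and zero FFNN second layer: residuals
  # make the layer the identity (layer norm off)
  cfg_id <- encoder_config(num_layers = 1, d_f = 8, heads = 2, pool_stride = 3,
                           dropout = 0, layernorm = FALSE)
  w <- init_encoder_layer(cfg_id, seed = 11)
  w$Wo[] <- 0; w$bo[] <- 0; w$W2[] <- 0; w$b2[] <- 0
  Z <- matrix(rnorm(8 * 20), 8, 20)
  expect_equal(encoder_layer(Z, w, cfg_id), Z, tolerance = 1e-12)
})

test_that("a shared encoder stack encodes every pyramid scale", {
  cfg_bb <- backbone_config("pyramid", d_f = 8, d_fe = 6)
  bb <- init_backbone(cfg_bb, seed = 1)
  pyr <- extract_features(rnorm(30000), bb, cfg_bb)
  cfg <- encoder_config(num_layers = 2, d_f = 8, heads = 2, pool_stride = 6,
                        dropout = 0)
  weights <- init_encoder(cfg, seed = 3)
  H <- encode(pyr, weights, cfg)
  expect_length(H, 3)
  expect_equal(vapply(H, ncol, numeric(1)), c(1200, 240, 48))
  expect_true(all(vapply(H, nrow, numeric(1)) == 8))

  # AvgFormer: only the pooling operator changes
  cfg_avg <- encoder_config(num_layers = 2, d_f = 8, heads = 2,
                            pool_mode = "avg", pool_stride = 6, dropout = 0)
  H_avg <- encode(pyr, weights, cfg_avg)
  expect_equal(vapply(H_avg, ncol, numeric(1)), c(1200, 240, 48))
  expect_false(isTRUE(all.equal(H[[3]], H_avg[[3]])))
})
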