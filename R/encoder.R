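#' Encoder configuration
#'
#' @param num_layers encoder depth (default 6).
#' @param d_f embedding dimension (default 128), divisible by `heads`.
#' @param heads attention heads (default 8).
#' @param ffnn_ratio hidden/embedding ratio of the FFNN (default 1).
#' @param pool_mode `"max"` (MaxFormer), `"avg"` (AvgFormer) or `"none"`
#'   (standard self-attention).
#' @param pool_stride kernel and stride of the key/value pooling (default 6).
#' @param R scale transition ratio for the hop-indexed positional encoding.
#' @param dropout dropout rate on attention weights and the FFNN hidden layer
#'   during training (default 0.1).
#' @param layernorm apply post-sublayer layer normalization (default TRUE).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(num_layers = 6, d_f = 128, heads = 8,
                           ffnn_ratio = 1, pool_mode = c("max", "avg", "none"),
                           pool_stride = 6, R = 5, dropout = 0.1,
                           layernorm = TRUE) {
  pool_mode <- match.arg(pool_mode)
  if (d_f %% heads != 0) stop("d_f must be divisible by the number of heads")
  if (pool_stride < 1) stop("pool_stride must be >= 1")
  if (ffnn_ratio <= 0) stop("ffnn_ratio must be positive")
  structure(list(num_layers = num_layers, d_f = d_f, heads = heads,
                 ffnn_ratio = ffnn_ratio, pool_mode = pool_mode,
                 pool_stride = pool_stride, R = R, dropout = dropout,
                 layernorm = layernorm),
            class = "encoder_config")
}

#' Hop-indexed sinusoidal positional encoding
#'
#' Coarser pyramid scales cover `R^(i-3)` fine-scale time steps per token, so
#' the token at position `t` (0-based) is encoded at the absolute position
#' `t * R^(i-3) + floor(R^(i-3) / 2)` (its window center on the finest
#' grid). Sinusoid frequencies follow the classic pairing: rows `2k` use
#' `sin`, rows `2k + 1` use `cos`, both at frequency `1 / 10000^(2k/d_f)`.
#' For `i = 3` this reduces exactly to the original sinusoidal encoding.
#'
#' @param i scale id (>= 3; `i = 3` is the finest scale).
#' @param T sequence length (tokens).
#' @param d_f embedding dimension.
#' @param R scale transition ratio (default 5).
#' @return matrix `d_f x T`.
#' @export
positional_encoding <- function(i, T, d_f, R = 5) {
  stopifnot(i >= 3, T >= 1, d_f >= 1)
  hop <- R^(i - 3)
  pos <- (0:(T - 1)) * hop + floor(hop / 2)
  j <- 0:(d_f - 1)
  freq <- 1 / 10000^(2 * (j %/% 2) / d_f)
  ang <- outer(freq, pos) # d_f x T
  P <- ang
  even <- j %% 2 == 0
  P[even, ] <- sin(ang[even, , drop = FALSE])
  P[!even, ] <- cos(ang[!even, , drop = FALSE])
  P
}

#' Add positional encoding to a feature sequence
#'
#' @param Z feature matrix `d_f x T`.
#' @param P positional encoding of identical shape.
#' @return elementwise sum.
#' @export
add_positional <- function(Z, P) {
  if (!all(dim(Z) == dim(P))) stop("shape mismatch between features and positional encoding")
  Z + P
}

#' Pool token sequences along time
#'
#' Windows of size `n` with stride `n`; per channel the window maximum
#' (MaxFormer) or mean (AvgFormer). The ragged tail window pools over its
#' valid entries. `n = 1` or mode `"none"` is the identity.
#'
#' @param Z feature matrix `d_f x T`.
#' @param n window size = stride (>= 1).
#' @param mode `"max"`, `"avg"` or `"none"`.
#' @return matrix `d_f x ceiling(T / n)`.
#' @export
pool_tokens <- function(Z, n, mode = c("max", "avg", "none")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  pool_fwd(Z, n, mode)$out
}

#' Initialize one encoder-layer weight set
#'
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return named parameter list (attention projections, layer norms, FFNN).
#' @export
init_encoder_layer <- function(config, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 41))
  d <- config$d_f
  dh <- round(config$ffnn_ratio * d)
  list(
    Wq = init_weight(d, d), bq = numeric(d),
    Wk = init_weight(d, d), bk = numeric(d),
    Wv = init_weight(d, d), bv = numeric(d),
    Wo = init_weight(d, d), bo = numeric(d),
    ln1_gamma = rep(1, d), ln1_beta = numeric(d),
    W1 = init_weight(dh, d), b1 = numeric(dh), slope = 0.25,
    W2 = init_weight(d, dh), b2 = numeric(d),
    ln2_gamma = rep(1, d), ln2_beta = numeric(d)
  )
}

#' Initialize a full encoder stack
#'
#' @inheritParams init_encoder_layer
#' @return list of per-layer weight sets, length `config$num_layers`.
#' @export
init_encoder <- function(config, seed = 1) {
  lapply(seq_len(config$num_layers), function(l) {
    init_encoder_layer(config, substream_seed(seed, 500 + l))
  })
}

# --- strided multi-head attention ------------------------------------------

attention_fwd <- function(Z, weights, config, train = FALSE) {
  d <- nrow(Z); T <- ncol(Z)
  h <- config$heads
  dk <- d / h
  pool <- pool_fwd(Z, config$pool_stride, config$pool_mode)
  A <- pool$out
  lq <- linear_fwd(weights$Wq, weights$bq, Z)
  lk <- linear_fwd(weights$Wk, weights$bk, A)
  lv <- linear_fwd(weights$Wv, weights$bv, A)
  Q <- lq$out; K <- lk$out; V <- lv$out
  O <- matrix(0, d, T)
  heads <- vector("list", h)
  for (hh in seq_len(h)) {
    rows <- ((hh - 1) * dk + 1):(hh * dk)
    S <- crossprod(Q[rows, , drop = FALSE], K[rows, , drop = FALSE]) / sqrt(dk)
    P <- softmax_rows(S)
    dp <- dropout_fwd(P, config$dropout, train)
    O[rows, ] <- V[rows, , drop = FALSE] %*% t(dp$out)
    heads[[hh]] <- list(P = P, Pd = dp$out, dmask = dp$cache, rows = rows)
  }
  lo <- linear_fwd(weights$Wo, weights$bo, O)
  list(out = lo$out,
       cache = list(pool = pool$cache, lq = lq$cache, lk = lk$cache,
                    lv = lv$cache, lo = lo$cache, Q = Q, K = K, V = V,
                    O = O, heads = heads, dk = dk))
}

attention_bwd <- function(dout, cache, weights) {
  lb <- linear_bwd(dout, cache$lo)
  dO <- lb$dX
  g <- list(Wo = lb$dW, bo = lb$db)
  d <- nrow(dO); T <- ncol(dO)
  dQ <- matrix(0, d, T)
  dK <- matrix(0, d, ncol(cache$K))
  dV <- matrix(0, d, ncol(cache$V))
  for (hd in cache$heads) {
    rows <- hd$rows
    dOh <- dO[rows, , drop = FALSE]
    Vh <- cache$V[rows, , drop = FALSE]
    dPd <- crossprod(dOh, Vh)            # T x Tp
    dV[rows, ] <- dOh %*% hd$Pd
    dP <- dropout_bwd(dPd, hd$dmask)
    dS <- softmax_rows_bwd(dP, hd$P)
    Kh <- cache$K[rows, , drop = FALSE]
    Qh <- cache$Q[rows, , drop = FALSE]
    dQ[rows, ] <- (Kh %*% t(dS)) / sqrt(cache$dk)
    dK[rows, ] <- (Qh %*% dS) / sqrt(cache$dk)
  }
  bq <- linear_bwd(dQ, cache$lq)
  bk <- linear_bwd(dK, cache$lk)
  bv <- linear_bwd(dV, cache$lv)
  g$Wq <- bq$dW; g$bq <- bq$db
  g$Wk <- bk$dW; g$bk <- bk$db
  g$Wv <- bv$dW; g$bv <- bv$db
  dA <- bk$dX + bv$dX
  dZ <- bq$dX + pool_bwd(dA, cache$pool)
  list(dZ = dZ, grads = g)
}

#' Strided multi-head attention (MaxFormer attention)
#'
#' Queries are projected from the full-length token sequence; keys and values
#' are projected from the pooled sequence (length `ceiling(T / n)`). Per
#' head, scores `Q' K / sqrt(d_k)` are softmax-normalized over the pooled
#' positions and applied to the values; heads are concatenated and
#' output-projected. With `pool_mode = "none"` (or `n = 1`) this is exactly
#' standard multi-head self-attention.
#'
#' @param Z feature matrix `d_f x T`.
#' @param weights layer weights from [init_encoder_layer()] (the attention
#'   entries are used).
#' @param config an [encoder_config()].
#' @return matrix `d_f x T`.
#' @export
strided_multihead_attention <- function(Z, weights, config) {
  attention_fwd(Z, weights, config, train = FALSE)$out
}

# --- full encoder layer -----------------------------------------------------

encoder_layer_fwd <- function(Z, weights, config, train = FALSE) {
  att <- attention_fwd(Z, weights, config, train)
  R1 <- Z + att$out
  if (config$layernorm) {
    ln1 <- layernorm_fwd(R1, weights$ln1_gamma, weights$ln1_beta)
    Z1 <- ln1$out
  } else {
    ln1 <- NULL; Z1 <- R1
  }
  l1 <- linear_fwd(weights$W1, weights$b1, Z1)
  a1 <- prelu_fwd(l1$out, weights$slope)
  dp <- dropout_fwd(a1$out, config$dropout, train)
  l2 <- linear_fwd(weights$W2, weights$b2, dp$out)
  R2 <- Z1 + l2$out
  if (config$layernorm) {
    ln2 <- layernorm_fwd(R2, weights$ln2_gamma, weights$ln2_beta)
    out <- ln2$out
  } else {
    ln2 <- NULL; out <- R2
  }
  list(out = out,
       cache = list(att = att$cache, ln1 = ln1$cache, l1 = l1$cache,
                    a1 = a1$cache, dp = dp$cache, l2 = l2$cache,
                    ln2 = ln2$cache, layernorm = config$layernorm))
}

encoder_layer_bwd <- function(dout, cache, weights) {
  g <- list()
  if (cache$layernorm) {
    lb2 <- layernorm_bwd(dout, cache$ln2)
    g$ln2_gamma <- lb2$dgamma; g$ln2_beta <- lb2$dbeta
    dR2 <- lb2$dX
  } else dR2 <- dout
  b2 <- linear_bwd(dR2, cache$l2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dh <- dropout_bwd(b2$dX, cache$dp)
  ab <- prelu_bwd(dh, cache$a1)
  g$slope <- ab$dslope
  b1 <- linear_bwd(ab$dX, cache$l1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  dZ1 <- dR2 + b1$dX # residual
  if (cache$layernorm) {
    lb1 <- layernorm_bwd(dZ1, cache$ln1)
    g$ln1_gamma <- lb1$dgamma; g$ln1_beta <- lb1$dbeta
    dR1 <- lb1$dX
  } else dR1 <- dZ1
  attb <- attention_bwd(dR1, cache$att, weights)
  g <- c(g, attb$grads)
  dZ <- dR1 + attb$dZ # residual
  list(dZ = dZ, grads = g[names(weights)])
}

#' One encoder layer (attention + FFNN, residuals, optional layer norm)
#'
#' Attention sublayer followed by a two-layer PReLU FFNN (hidden size
#' `ffnn_ratio * d_f`), each wrapped in a residual connection, with
#' post-sublayer layer normalization when `config$layernorm` is on.
#'
#' @inheritParams strided_multihead_attention
#' @return matrix `d_f x T`.
#' @export
encoder_layer <- function(Z, weights, config) {
  encoder_layer_fwd(Z, weights, config, train = FALSE)$out
}

encode_fwd <- function(pyramid_Ftilde, scale_ids, enc_weights, config,
                       train = FALSE, add_pe = TRUE) {
  H <- vector("list", length(pyramid_Ftilde))
  caches <- vector("list", length(pyramid_Ftilde))
  for (s in seq_along(pyramid_Ftilde)) {
    Z <- pyramid_Ftilde[[s]]
    if (add_pe) {
      Z <- add_positional(Z, positional_encoding(scale_ids[s], ncol(Z),
                                                 nrow(Z), config$R))
    }
    lc <- vector("list", length(enc_weights))
    for (l in seq_along(enc_weights)) {
      st <- encoder_layer_fwd(Z, enc_weights[[l]], config, train)
      Z <- st$out
      lc[[l]] <- st$cache
    }
    H[[s]] <- Z
    caches[[s]] <- lc
  }
  list(H = H, caches = caches)
}

encode_bwd <- function(dH, caches, enc_weights) {
  g <- tree_zeros(enc_weights)
  dF <- vector("list", length(dH))
  for (s in seq_along(dH)) {
    dZ <- dH[[s]]
    for (l in rev(seq_along(enc_weights))) {
      st <- encoder_layer_bwd(dZ, caches[[s]][[l]], enc_weights[[l]])
      dZ <- st$dZ
      g[[l]] <- tree_add(g[[l]], st$grads)
    }
    dF[[s]] <- dZ # positional encoding is additive: gradient passes through
  }
  list(dF = dF, grads = g)
}

#' Encode a feature pyramid with one shared encoder stack
#'
#' Adds the hop-indexed positional encoding per scale and applies the same
#' stack of encoder layers to every scale.
#'
#' @param pyramid a `feature_pyramid` (see [extract_features()]) whose
#'   feature matrices are already in the shared embedding space.
#' @param enc_weights list of layer weights from [init_encoder()].
#' @param config an [encoder_config()].
#' @return list of encoded matrices `H_i` (`d_f x T_i`), one per scale.
#' @export
encode <- function(pyramid, enc_weights, config) {
  Fs <- lapply(pyramid$scales, `[[`, "F")
  ids <- vapply(pyramid$scales, `[[`, numeric(1), "i")
  encode_fwd(Fs, ids, enc_weights, config, train = FALSE)$H
}
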