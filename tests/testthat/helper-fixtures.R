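# Shared fixtures, built in code. The cache avoids regenerating the same
# synthetic data across test files.

.fixture_env <- new.env()

tiny_model <- function(pool_mode = "max", seed = 3, d_f = 8, layers = 2,
                       mode = "pyramid", dropout = 0, layernorm = TRUE,
                       pool_stride = 3) {
  bb <- backbone_config(mode, d_f = d_f, d_fe = 6, base_reduction = 25, R = 5)
  enc <- encoder_config(num_layers = layers, d_f = d_f, heads = 2,
                        ffnn_ratio = 1, pool_mode = pool_mode,
                        pool_stride = pool_stride, dropout = dropout,
                        layernorm = layernorm)
  sleep_model(model_config(bb, enc, L = 1, d_proj = 7), seed = seed)
}

small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_dataset(4, 40, seed = 77)
  }
  .fixture_env$small
}

# direct nested-loop multi-head attention oracle: queries from Z, keys and
# values from the pooled sequence A, per-head softmax over pooled positions
oracle_strided_attention <- function(Z, A, w, h) {
  d <- nrow(Z); T <- ncol(Z); Tp <- ncol(A)
  dk <- d / h
  Q <- w$Wq %*% Z + w$bq
  K <- w$Wk %*% A + w$bk
  V <- w$Wv %*% A + w$bv
  O <- matrix(0, d, T)
  for (hh in seq_len(h)) {
    rows <- ((hh - 1) * dk + 1):(hh * dk)
    for (t in seq_len(T)) {
      scores <- numeric(Tp)
      for (p in seq_len(Tp)) {
        scores[p] <- sum(Q[rows, t] * K[rows, p]) / sqrt(dk)
      }
      wts <- exp(scores - max(scores))
      wts <- wts / sum(wts)
      acc <- numeric(dk)
      for (p in seq_len(Tp)) acc <- acc + wts[p] * V[rows, p]
      O[rows, t] <- acc
    }
  }
  w$Wo %*% O + w$bo
}

# literal double-loop Supcon oracle
oracle_supcon <- function(Z, labels, tau) {
  n <- ncol(Z)
  labels <- as.character(labels)
  total <- 0
  for (p in seq_len(n)) {
    Np <- setdiff(seq_len(n), p)
    Pp <- Np[labels[Np] == labels[p]]
    if (length(Pp) == 0) next
    denom <- 0
    for (k in Np) denom <- denom + exp(sum(Z[, p] * Z[, k]) / tau)
    for (q in Pp) {
      total <- total - log(exp(sum(Z[, p] * Z[, q]) / tau) / denom) / length(Pp)
    }
  }
  total
}

# brute-force per-class tallies from label pairs
oracle_metrics <- function(cm) {
  stages <- rownames(cm)
  f1 <- numeric(5)
  for (i in 1:5) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    re <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  }
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  list(accuracy = po, f1 = f1, mf1 = mean(f1), kappa = (po - pe) / (1 - pe))
}

random_unit_cols <- function(d, n, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(d * n), d, n)
  sweep(Z, 2, sqrt(colSums(Z^2)), `/`)
}
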