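#' Initialize the attention-based sleep stage classifier (AS2C)
#'
#' A state-transform FC layer maps encoder outputs to attention states, a
#' learnable context vector scores each state through a tanh nonlinearity,
#' softmax weights aggregate the states over time, and a final FC layer maps
#' the pooled vector to the 5 stage logits.
#'
#' @param d_f embedding dimension.
#' @param seed integer seed.
#' @param mean_pool use plain mean pooling instead of learned attention
#'   (the "conventional fully connected" ablation head).
#' @return named parameter list of class `as2c_weights`.
#' @export
init_as2c <- function(d_f, seed = 1, mean_pool = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 51))
  structure(list(
    Ws = init_weight(d_f, d_f), bs = numeric(d_f),
    u = stats::runif(d_f, -sqrt(3 / d_f), sqrt(3 / d_f)),
    Wa = init_weight(5, d_f), ba = numeric(5),
    mean_pool = mean_pool
  ), class = "as2c_weights")
}

as2c_pool_fwd <- function(H, weights) {
  ls <- linear_fwd(weights$Ws, weights$bs, H)
  a <- ls$out # attention states, d_f x T
  if (isTRUE(weights$mean_pool)) {
    alpha <- rep(1 / ncol(a), ncol(a))
    th <- NULL
  } else {
    th <- tanh(a)
    e <- as.numeric(crossprod(th, weights$u))
    alpha <- softmax_vec(e)
  }
  abar <- as.numeric(a %*% alpha)
  list(abar = abar, alpha = alpha,
       cache = list(ls = ls$cache, a = a, th = th, alpha = alpha))
}

as2c_pool_bwd <- function(dabar, cache, weights) {
  a <- cache$a
  alpha <- cache$alpha
  da <- outer(dabar, alpha) # from abar = a %*% alpha
  g <- list(u = numeric(length(weights$u)))
  if (!isTRUE(weights$mean_pool)) {
    dalpha <- as.numeric(crossprod(a, dabar))
    de <- alpha * (dalpha - sum(dalpha * alpha))
    g$u <- as.numeric(cache$th %*% de)
    da <- da + sweep(weights$u * (1 - cache$th^2), 2, de, `*`)
  }
  lb <- linear_bwd(da, cache$ls)
  g$Ws <- lb$dW; g$bs <- lb$db
  list(dH = lb$dX, grads = g)
}

#' Temporal attention pooling of an encoded sequence
#'
#' Softmax attention weights over time (nonnegative, summing to one) applied
#' to the attention states, yielding a single `d_f` vector inside the convex
#' hull of the states.
#'
#' @param H encoded feature matrix `d_f x T`.
#' @param weights [init_as2c()] parameters.
#' @return list with `abar` (pooled `d_f` vector) and `alpha` (the `T`
#'   attention weights).
#' @export
attention_pool <- function(H, weights) {
  f <- as2c_pool_fwd(H, weights)
  list(abar = f$abar, alpha = f$alpha)
}

#' Per-scale stage logits
#'
#' Affine map of the pooled attention vector to the 5 stage logits
#' (order W, N1, N2, N3, REM).
#'
#' @param abar pooled `d_f` vector.
#' @param weights [init_as2c()] parameters.
#' @return numeric length-5 logit vector.
#' @export
scale_logits <- function(abar, weights) {
  as.numeric(weights$Wa %*% abar + weights$ba)
}

#' Fuse per-scale logits and predict the stage
#'
#' Elementwise sum of the per-scale logit vectors followed by argmax; ties
#' break deterministically to the lowest class index.
#'
#' @param logits list of length-5 logit vectors (1 for single-scale
#'   backbones, 3 for the pyramid).
#' @return list with `stage` (factor level), `index` (1..5), `fused` (summed
#'   logits).
#' @export
fuse_predict <- function(logits) {
  if (!is.list(logits)) logits <- list(logits)
  fused <- Reduce(`+`, logits)
  idx <- which.max(fused) # first maximum = lowest class index on ties
  list(stage = factor(SLEEP_STAGES[idx], levels = SLEEP_STAGES),
       index = idx, fused = fused)
}

# forward over all scales with caches
as2c_fwd <- function(H_list, weights) {
  pools <- lapply(H_list, as2c_pool_fwd, weights = weights)
  logits <- lapply(pools, function(p) scale_logits(p$abar, weights))
  list(logits = logits, pools = pools)
}

# dlogits: list of length-5 gradients per scale
as2c_bwd <- function(dlogits, fwd, weights) {
  g <- tree_zeros(weights[c("Ws", "bs", "u", "Wa", "ba")])
  dH <- vector("list", length(dlogits))
  for (s in seq_along(dlogits)) {
    dl <- dlogits[[s]]
    abar <- fwd$pools[[s]]$abar
    g$Wa <- g$Wa + outer(dl, abar)
    g$ba <- g$ba + dl
    dabar <- as.numeric(crossprod(weights$Wa, dl))
    pb <- as2c_pool_bwd(dabar, fwd$pools[[s]]$cache, weights)
    g$Ws <- g$Ws + pb$grads$Ws
    g$bs <- g$bs + pb$grads$bs
    g$u <- g$u + pb$grads$u
    dH[[s]] <- pb$dH
  }
  list(dH = dH, grads = g)
}
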