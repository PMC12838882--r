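# Internal neural-net primitives. Features are matrices d x T (rows =
# channels, columns = time tokens). Every *_fwd returns list(out, cache);
# every *_bwd takes (dout, cache) and returns the input gradient plus
# parameter gradients. No autodiff framework exists in this environment, so
# gradients are derived by hand and pinned by finite-difference tests.

linear_fwd <- function(W, b, X) {
  list(out = W %*% X + b, cache = list(W = W, X = X))
}

linear_bwd <- function(dout, cache) {
  list(dX = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$X),
       db = rowSums(dout))
}

prelu_fwd <- function(X, slope) {
  pos <- X > 0
  list(out = ifelse(pos, X, slope * X), cache = list(X = X, pos = pos, slope = slope))
}

prelu_bwd <- function(dout, cache) {
  list(dX = dout * ifelse(cache$pos, 1, cache$slope),
       dslope = sum(dout * cache$X * !cache$pos))
}

relu_fwd <- function(X) {
  pos <- X > 0
  list(out = X * pos, cache = pos)
}

relu_bwd <- function(dout, cache) dout * cache

# layer normalization over channels, per token (column)
layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- xhat * gamma + beta
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- dout * cache$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dX <- sweep(dX, 2, cache$inv, `*`)
  list(dX = dX, dgamma = rowSums(dout * xhat), dbeta = rowSums(dout))
}

# row-wise softmax of a score matrix
softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

softmax_rows_bwd <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

softmax_vec <- function(e) {
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

# window pooling over time: kernel = stride = n, ceiling(T/n) windows, the
# ragged tail window pools over its valid entries only
pool_fwd <- function(Z, n, mode = c("max", "avg", "none")) {
  mode <- match.arg(mode)
  if (mode == "none" || n == 1) {
    return(list(out = Z, cache = list(mode = "none", dim = dim(Z))))
  }
  d <- nrow(Z); T <- ncol(Z)
  Tp <- ceiling(T / n)
  A <- matrix(0, d, Tp)
  if (mode == "max") {
    argmax <- matrix(0L, d, Tp)
    for (w in seq_len(Tp)) {
      cols <- ((w - 1) * n + 1):min(w * n, T)
      blk <- Z[, cols, drop = FALSE]
      ix <- max.col(blk, ties.method = "first")
      A[, w] <- blk[cbind(seq_len(d), ix)]
      argmax[, w] <- cols[ix]
    }
    cache <- list(mode = "max", argmax = argmax, dim = dim(Z), n = n)
  } else {
    width <- integer(Tp)
    for (w in seq_len(Tp)) {
      cols <- ((w - 1) * n + 1):min(w * n, T)
      width[w] <- length(cols)
      A[, w] <- rowMeans(Z[, cols, drop = FALSE])
    }
    cache <- list(mode = "avg", width = width, dim = dim(Z), n = n)
  }
  list(out = A, cache = cache)
}

pool_bwd <- function(dA, cache) {
  if (cache$mode == "none") return(dA)
  d <- cache$dim[1]; T <- cache$dim[2]
  dZ <- matrix(0, d, T)
  Tp <- ncol(dA)
  if (cache$mode == "max") {
    for (w in seq_len(Tp)) {
      idx <- cbind(seq_len(d), cache$argmax[, w])
      dZ[idx] <- dZ[idx] + dA[, w]
    }
  } else {
    for (w in seq_len(Tp)) {
      cols <- ((w - 1) * cache$n + 1):min(w * cache$n, T)
      dZ[, cols] <- dZ[, cols] + dA[, w] / cache$width[w]
    }
  }
  dZ
}

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# --- parameter-tree helpers (nested named lists of numerics) ---------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

tree_flatten <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  do.call(c, lapply(tree, tree_flatten))
}

tree_max_abs_diff <- function(a, b) {
  af <- tree_flatten(a)
  bf <- tree_flatten(b)
  max(vapply(seq_along(af), function(i) max(abs(af[[i]] - bf[[i]])), numeric(1)))
}

# Xavier-uniform initial weights
init_weight <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}
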