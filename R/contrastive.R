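#' Initialize the contrastive projection head
#'
#' Global average pooling over time, then a two-layer MLP
#' `FC(d_f -> 128) -> ReLU -> FC(128 -> 128)`; projections are
#' L2-normalized onto the unit hypersphere before any similarity is taken.
#'
#' @param d_f input embedding dimension.
#' @param d_proj projection dimension (default 128).
#' @param seed integer seed.
#' @return named parameter list.
#' @export
init_projector <- function(d_f, d_proj = 128, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 61))
  list(W1 = init_weight(d_proj, d_f), b1 = numeric(d_proj),
       W2 = init_weight(d_proj, d_proj), b2 = numeric(d_proj))
}

projector_fwd <- function(H, params, eps = 1e-12) {
  p <- rowMeans(H)
  l1 <- params$W1 %*% p + params$b1
  r1 <- pmax(l1, 0)
  u <- as.numeric(params$W2 %*% r1 + params$b2)
  nu <- sqrt(sum(u^2))
  z <- u / max(nu, eps)
  list(z = z, cache = list(p = p, l1 = as.numeric(l1), r1 = as.numeric(r1),
                           u = u, nu = max(nu, eps), T = ncol(H)))
}

projector_bwd <- function(dz, cache, params) {
  # through z = u / ||u||
  z <- cache$u / cache$nu
  du <- (dz - sum(dz * z) * z) / cache$nu
  g <- list()
  g$W2 <- outer(du, cache$r1)
  g$b2 <- du
  dr1 <- as.numeric(crossprod(params$W2, du))
  dl1 <- dr1 * (cache$l1 > 0)
  g$W1 <- outer(dl1, cache$p)
  g$b1 <- dl1
  dp <- as.numeric(crossprod(params$W1, dl1))
  dH <- matrix(dp / cache$T, length(dp), cache$T)
  list(dH = dH, grads = g[c("W1", "b1", "W2", "b2")])
}

#' Project encoded features onto the contrastive hypersphere
#'
#' @param H_list list of encoded matrices `d_f x T_i`, one per scale.
#' @param params projector weights from [init_projector()].
#' @return matrix `d_proj x n_scales` of unit-norm projections (one column
#'   per scale).
#' @export
project_features <- function(H_list, params) {
  if (!is.list(H_list)) H_list <- list(H_list)
  vapply(H_list, function(H) projector_fwd(H, params)$z,
         numeric(nrow(params$W2)))
}

#' Cosine similarity
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# loss + gradient w.r.t. the (unit-norm) projection columns
supcon_grad <- function(Z, labels, tau = 0.07) {
  n <- ncol(Z)
  if (n < 2) stop("supervised contrastive loss needs a batch of size >= 2")
  labels <- as.character(labels)
  S <- crossprod(Z) / tau
  G <- matrix(0, n, n)
  loss <- 0
  skipped <- 0
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    pos <- others[labels[others] == labels[p]]
    if (length(pos) == 0) {
      skipped <- skipped + 1
      next
    }
    s <- S[p, others]
    m <- max(s)
    lse <- m + log(sum(exp(s - m)))
    w <- exp(s - lse) # softmax over the denominator set N_p
    loss <- loss - sum(S[p, pos] - lse) / length(pos)
    G[p, others] <- w
    G[p, pos] <- G[p, pos] - 1 / length(pos)
  }
  if (skipped > 0) {
    warning(sprintf("%d anchor(s) without positives skipped in Supcon loss", skipped))
  }
  dZ <- Z %*% (G + t(G)) / tau
  list(loss = loss, dZ = dZ)
}

#' Supervised contrastive (Supcon) loss over a multiview batch
#'
#' For each anchor `p`, positives `P_p` are the other same-label samples in
#' the multiview batch; the denominator runs over all other samples `N_p`:
#' \deqn{L = -\sum_p \frac{1}{|P_p|} \sum_{q \in P_p}
#'   \log \frac{\exp(z_p \cdot z_q / \tau)}{\sum_{k \in N_p} \exp(z_p \cdot z_k / \tau)}}
#' Anchors without positives are skipped with a warning.
#'
#' @param Z matrix of unit-norm projections, one column per sample
#'   (`2 N_b` columns for a multiview batch).
#' @param labels per-column class labels.
#' @param tau temperature (> 0), default 0.07.
#' @return scalar loss (>= 0 in the regimes of interest).
#' @export
supcon_loss <- function(Z, labels, tau = 0.07) {
  stopifnot(tau > 0)
  supcon_grad(Z, labels, tau)$loss
}

#' Multi-scale Supcon loss
#'
#' Sum of the per-scale Supcon losses.
#'
#' @param Z_list list of projection matrices (one per scale, samples as
#'   columns).
#' @param labels per-sample labels (shared by all scales).
#' @param tau temperature.
#' @return scalar total loss.
#' @export
multiscale_supcon <- function(Z_list, labels, tau = 0.07) {
  if (!is.list(Z_list)) Z_list <- list(Z_list)
  sum(vapply(Z_list, supcon_loss, numeric(1), labels = labels, tau = tau))
}
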