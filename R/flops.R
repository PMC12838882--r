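#' Analytic forward-pass FLOPs of one encoder layer
#'
#' Closed-form multiply-accumulate counts for a single Transformer encoder
#' layer, in the accounting where one multiply-accumulate = 1 FLOP and
#' softmax, layer-norm, bias and activation costs are excluded.
#'
#' For token sequence length `L` and model width `d` with FFNN expansion
#' ratio `r`:
#' \deqn{FLOPs_{std} = (4 + 2r) L d^2 + 2 L^2 d}
#' For the max-pooled variant, keys and values are shortened to `L/n` before
#' projection while queries stay full length:
#' \deqn{FLOPs_{max} = (2 + 2/n + 2r) L d^2 + 2 L^2 d / n}
#' At `n = 1` the two expressions coincide.
#'
#' Note `L` here is the token sequence length seen by the encoder (e.g. 1200
#' for the finest pyramid scale of a 10-epoch input), not the number of
#' 30-second sleep epochs.
#'
#' @param variant `"standard"` or `"max"` (the avg-pool variant has the same
#'   count as `"max"`).
#' @param L token sequence length (>= 1).
#' @param d model width (>= 1).
#' @param r FFNN expansion ratio (> 0), default 1.
#' @param n pooling stride (>= 1); ignored for `"standard"`.
#' @return object of class `flops_breakdown`: list with `projection_flops`,
#'   `attention_flops`, `ffnn_flops`, `total_forward`, `total_training`, and
#'   the inputs.
#' @export
forward_flops <- function(variant = c("standard", "max"), L, d, r = 1, n = 1) {
  variant <- match.arg(variant)
  stopifnot(L >= 1, d >= 1, r > 0, n >= 1)
  if (variant == "standard") {
    proj <- 4 * L * d^2
    attn <- 2 * L^2 * d
  } else {
    proj <- (2 + 2 / n) * L * d^2
    attn <- 2 * L^2 * d / n
  }
  ffnn <- 2 * r * L * d^2
  out <- list(
    variant = variant, L = L, d = d, r = r,
    n = if (variant == "max") n else 1,
    projection_flops = proj,
    attention_flops = attn,
    ffnn_flops = ffnn,
    total_forward = proj + attn + ffnn
  )
  out$total_training <- 3 * out$total_forward
  class(out) <- "flops_breakdown"
  out
}

#' @export
print.flops_breakdown <- function(x, ...) {
  cat(sprintf("%s encoder layer, L=%d d=%d r=%g%s\n", x$variant, x$L, x$d,
              x$r, if (x$variant == "max") sprintf(" n=%d", x$n) else ""))
  cat(sprintf("  QKVO projections: %s\n", format(x$projection_flops, big.mark = ",")))
  cat(sprintf("  attention (scores + aggregation): %s\n",
              format(x$attention_flops, big.mark = ",")))
  cat(sprintf("  FFNN: %s\n", format(x$ffnn_flops, big.mark = ",")))
  cat(sprintf("  total forward: %s\n", format(x$total_forward, big.mark = ",")))
  cat(sprintf("  total training (3x forward): %s\n",
              format(x$total_training, big.mark = ",")))
  invisible(x)
}

#' Training FLOPs from a forward breakdown
#'
#' Backward propagation roughly doubles the cost of each linear operation
#' (gradients w.r.t. both activations and parameters), so training cost per
#' layer is accounted as exactly three forward passes.
#'
#' @param breakdown a `flops_breakdown` from [forward_flops()].
#' @return numeric: `3 * total_forward`.
#' @export
training_flops <- function(breakdown) {
  stopifnot(inherits(breakdown, "flops_breakdown"))
  3 * breakdown$total_forward
}

#' Quadratic-term approximation of layer cost
#'
#' In the long-sequence regime (L >> d) the attention score/aggregation term
#' dominates: standard ~ 2 L^2 d, max-pooled ~ 2 L^2 d / n. Returns the
#' approximation together with its relative error against the full closed
#' form.
#'
#' @inheritParams forward_flops
#' @return list with `standard`, `max`, `relative_error_standard`,
#'   `relative_error_max`.
#' @export
dominant_term <- function(L, d, n = 1, r = 1) {
  full_std <- forward_flops("standard", L, d, r)$total_forward
  full_max <- forward_flops("max", L, d, r, n)$total_forward
  approx_std <- 2 * L^2 * d
  approx_max <- 2 * L^2 * d / n
  list(
    standard = approx_std,
    max = approx_max,
    relative_error_standard = abs(approx_std - full_std) / full_std,
    relative_error_max = abs(approx_max - full_max) / full_max
  )
}

#' Percentage FLOPs reduction of the max-pooled layer
#'
#' `100 * (1 - max / standard)` at the given operating point.
#'
#' @inheritParams forward_flops
#' @param digits rounding for the returned percentage; `NULL` for unrounded.
#' @export
flops_reduction <- function(L, d, r = 1, n = 1, digits = NULL) {
  std <- forward_flops("standard", L, d, r)$total_forward
  mx <- forward_flops("max", L, d, r, n)$total_forward
  pct <- 100 * (1 - mx / std)
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Count scalar multiplications of one real encoder-layer forward pass
#'
#' Executes an actual encoder layer on `Z` and tallies `a * b * c` for every
#' matrix product `(a x b) (b x c)` it performs (projections, per-head score
#' and aggregation products, FFNN). Softmax, bias, pooling and activation
#' operations are not counted, matching the accounting of the closed-form
#' model; the empirical count therefore serves as an oracle for
#' [forward_flops()].
#'
#' @param Z feature matrix `d_f x T`.
#' @param weights layer weights from [init_encoder_layer()].
#' @param config an [encoder_config()].
#' @return list with `count` (total multiplies) and `out` (the layer output,
#'   identical to [encoder_layer()]).
#' @export
empirical_multiply_count <- function(Z, weights, config) {
  counter <- 0
  mm <- function(A, B) {
    counter <<- counter + nrow(A) * ncol(A) * ncol(B)
    A %*% B
  }
  d <- nrow(Z); T <- ncol(Z)
  h <- config$heads; dk <- d / h
  A <- pool_fwd(Z, config$pool_stride, config$pool_mode)$out
  Q <- mm(weights$Wq, Z) + weights$bq
  K <- mm(weights$Wk, A) + weights$bk
  V <- mm(weights$Wv, A) + weights$bv
  O <- matrix(0, d, T)
  for (hh in seq_len(h)) {
    rows <- ((hh - 1) * dk + 1):(hh * dk)
    S <- mm(t(Q[rows, , drop = FALSE]), K[rows, , drop = FALSE]) / sqrt(dk)
    P <- softmax_rows(S)
    O[rows, ] <- mm(V[rows, , drop = FALSE], t(P))
  }
  Y <- mm(weights$Wo, O) + weights$bo
  R1 <- Z + Y
  if (config$layernorm) {
    R1 <- layernorm_fwd(R1, weights$ln1_gamma, weights$ln1_beta)$out
  }
  U <- prelu_fwd(mm(weights$W1, R1) + weights$b1, weights$slope)$out
  R2 <- R1 + (mm(weights$W2, U) + weights$b2)
  if (config$layernorm) {
    R2 <- layernorm_fwd(R2, weights$ln2_gamma, weights$ln2_beta)$out
  }
  list(count = counter, out = R2)
}
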