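#' Backbone (feature extractor) configuration
#'
#' The framework accepts any feature extractor that maps a raw
#' `3000 * L`-sample sequence to a pyramid of feature matrices of shape
#' `d_f x ceiling(3000 L / r_i)`. The built-in toy backbone realizes the
#' reduction factors with stacked non-overlapping strided 1-D convolutions
#' and PReLU; it makes the pipeline runnable and testable but does not
#' reproduce any published backbone.
#'
#' @param mode `"pyramid"` (three scales, reductions 25/125/625, scale ids
#'   3/4/5) or `"single"` (one scale).
#' @param d_f embedding width after the dimension transform (default 128).
#' @param d_fe channel width of the raw toy-backbone features (default
#'   `d_f`).
#' @param base_reduction reduction factor of the finest scale (default 25).
#' @param R reduction ratio between consecutive scales (default 5).
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(mode = c("pyramid", "single"), d_f = 128,
                            d_fe = d_f, base_reduction = 25, R = 5) {
  mode <- match.arg(mode)
  stopifnot(d_f >= 1, d_fe >= 1, base_reduction >= 1, R >= 2)
  reductions <- if (mode == "pyramid") {
    base_reduction * R^(0:2)
  } else base_reduction
  structure(list(mode = mode, d_f = d_f, d_fe = d_fe,
                 base_reduction = base_reduction, R = R,
                 reductions = reductions,
                 scale_ids = if (mode == "pyramid") 3:5 else 3L),
            class = "backbone_config")
}

#' Initialize toy-backbone weights
#'
#' @param config a [backbone_config()].
#' @param seed integer seed.
#' @return nested parameter list (patch conv, pyramid convs, dimension
#'   transform).
#' @export
init_backbone <- function(config, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 31))
  p <- list(
    patch = list(W = init_weight(config$d_fe, config$base_reduction),
                 b = numeric(config$d_fe), slope = 0.25),
    dt = list(W = init_weight(config$d_f, config$d_fe), b = numeric(config$d_f))
  )
  if (config$mode == "pyramid") {
    p$pyr1 <- list(W = init_weight(config$d_fe, config$d_fe * config$R),
                   b = numeric(config$d_fe), slope = 0.25)
    p$pyr2 <- list(W = init_weight(config$d_fe, config$d_fe * config$R),
                   b = numeric(config$d_fe), slope = 0.25)
  }
  p
}

#' Extract the multi-scale feature pyramid from a raw sequence
#'
#' @param x numeric vector of length `3000 * L` (L consecutive 30-s epochs at
#'   100 Hz).
#' @param params backbone weights from [init_backbone()].
#' @param config a [backbone_config()].
#' @return object of class `feature_pyramid`: list of scales, each with
#'   `i` (scale id), `r` (reduction), and `F` (`d_f x T_i` feature matrix,
#'   `T_i = ceiling(3000 L / r_i)`).
#' @export
extract_features <- function(x, params, config) {
  fwd <- backbone_fwd(x, params, config)
  fwd$pyramid
}

# forward with caches (internal; extract_features is the public facade)
backbone_fwd <- function(x, params, config) {
  n <- length(x)
  if (n %% 3000 != 0) stop("input length must be a multiple of 3000 samples")
  r0 <- config$base_reduction
  if (n %% r0 != 0) stop("input length must be divisible by the base reduction")
  patches <- matrix(x, nrow = r0) # non-overlapping windows as columns
  l1 <- linear_fwd(params$patch$W, params$patch$b, patches)
  a1 <- prelu_fwd(l1$out, params$patch$slope)
  raw <- list(a1$out)
  caches <- list(patches = patches, l1 = l1$cache, a1 = a1$cache)
  if (config$mode == "pyramid") {
    R <- config$R
    for (s in 1:2) {
      prev <- raw[[s]]
      Tprev <- ncol(prev)
      Tnext <- ceiling(Tprev / R)
      if (Tnext * R > Tprev) { # zero-pad the ragged tail window
        prev <- cbind(prev, matrix(0, nrow(prev), Tnext * R - Tprev))
      }
      stacked <- matrix(prev, nrow = nrow(prev) * R)
      pw <- params[[paste0("pyr", s)]]
      lf <- linear_fwd(pw$W, pw$b, stacked)
      af <- prelu_fwd(lf$out, pw$slope)
      raw[[s + 1]] <- af$out
      caches[[paste0("pyr", s)]] <- list(l = lf$cache, a = af$cache,
                                         prev_dim = dim(prev),
                                         orig_cols = Tprev)
    }
  }
  scales <- vector("list", length(raw))
  dtc <- vector("list", length(raw))
  for (s in seq_along(raw)) {
    dt <- linear_fwd(params$dt$W, params$dt$b, raw[[s]])
    dtc[[s]] <- dt$cache
    scales[[s]] <- list(i = config$scale_ids[s], r = config$reductions[s],
                        F = dt$out)
  }
  caches$dt <- dtc
  caches$raw <- raw
  pyr <- structure(list(scales = scales, L = n / 3000), class = "feature_pyramid")
  list(pyramid = pyr, cache = caches)
}

# dF: list of gradients at the dimension-transform outputs, one per scale
backbone_bwd <- function(dF, cache, params, config) {
  g <- tree_zeros(params)
  n_scales <- length(dF)
  draw <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    lb <- linear_bwd(dF[[s]], cache$dt[[s]])
    g$dt$W <- g$dt$W + lb$dW
    g$dt$b <- g$dt$b + lb$db
    draw[[s]] <- lb$dX
  }
  if (config$mode == "pyramid") {
    for (s in 2:1) {
      cc <- cache[[paste0("pyr", s)]]
      ab <- prelu_bwd(draw[[s + 1]], cc$a)
      lb <- linear_bwd(ab$dX, cc$l)
      g[[paste0("pyr", s)]]$W <- lb$dW
      g[[paste0("pyr", s)]]$b <- lb$db
      g[[paste0("pyr", s)]]$slope <- ab$dslope
      dprev <- matrix(lb$dX, nrow = cc$prev_dim[1])
      draw[[s]] <- draw[[s]] + dprev[, seq_len(cc$orig_cols), drop = FALSE]
    }
  }
  ab <- prelu_bwd(draw[[1]], cache$a1)
  lb <- linear_bwd(ab$dX, cache$l1)
  g$patch$W <- lb$dW
  g$patch$b <- lb$db
  g$patch$slope <- ab$dslope
  g
}

#' Dimension transform (1-D convolution with kernel 1)
#'
#' Pure channel mixing mapping `d_in`-channel features to `d_f` channels;
#' temporal length is unchanged.
#'
#' @param F feature matrix `d_in x T`.
#' @param W weight matrix `d_f x d_in`.
#' @param b bias vector length `d_f` (default zeros).
#' @return matrix `d_f x T`.
#' @export
dimension_transform <- function(F, W, b = numeric(nrow(W))) {
  W %*% F + b
}

#' Shared embedding projection (FC + PReLU)
#'
#' One weight set shared by all pyramid scales, projecting features from the
#' convolutional scales into the common embedding space consumed by the
#' sequence encoder.
#'
#' @param F feature matrix `d_f x T`.
#' @param params list with `W` (`d_f x d_f`), `b`, `slope` (PReLU).
#' @return matrix `d_f x T`.
#' @export
shared_projection <- function(F, params) {
  prelu_fwd(params$W %*% F + params$b, params$slope)$out
}

init_shared_projection <- function(d_f, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 32))
  list(W = init_weight(d_f, d_f), b = numeric(d_f), slope = 0.25)
}
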