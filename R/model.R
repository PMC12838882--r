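#' Full model configuration
#'
#' @param backbone a [backbone_config()].
#' @param encoder an [encoder_config()] (its `d_f` must match the backbone's).
#' @param L number of consecutive 30-s epochs per input sequence (default
#'   10, which gives pyramid token lengths 1200/240/48).
#' @param d_proj contrastive projection dimension (default 128).
#' @return list of class `model_config`.
#' @export
model_config <- function(backbone = backbone_config(), encoder = encoder_config(),
                         L = 10, d_proj = 128) {
  if (backbone$d_f != encoder$d_f) stop("backbone and encoder d_f must match")
  stopifnot(L >= 1)
  structure(list(backbone = backbone, encoder = encoder, L = L,
                 d_proj = d_proj),
            class = "model_config")
}

#' Build a sleep staging model with freshly initialized weights
#'
#' Parameter groups: `fe` (feature extractor + dimension transform),
#' `shared` (shared FC + PReLU embedding projection), `tse` (encoder stack),
#' `projector` (contrastive head), `as2c` (classifier).
#'
#' @param config a [model_config()].
#' @param seed integer seed for initialization.
#' @return object of class `sleep_model`.
#' @export
sleep_model <- function(config = model_config(), seed = 1) {
  params <- list(
    fe = init_backbone(config$backbone, substream_seed(seed, 1)),
    shared = init_shared_projection(config$backbone$d_f, substream_seed(seed, 2)),
    tse = init_encoder(config$encoder, substream_seed(seed, 3)),
    projector = init_projector(config$backbone$d_f, config$d_proj,
                               substream_seed(seed, 4)),
    as2c = unclass(init_as2c(config$backbone$d_f, substream_seed(seed, 5)))
  )
  structure(list(params = params, config = config), class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(tree_flatten(lapply(x$params, function(p) {
    p[!vapply(p, is.logical, logical(1))]
  })), length, integer(1)))
  cat(sprintf(paste0(
    "sleep staging model: %s backbone, %d encoder layer(s) (%s pooling, ",
    "stride %d), d_f = %d, heads = %d, L = %d, ~%d parameters\n"),
    cfg$backbone$mode, cfg$encoder$num_layers, cfg$encoder$pool_mode,
    cfg$encoder$pool_stride, cfg$encoder$d_f, cfg$encoder$heads, cfg$L, n_par))
  invisible(x)
}

# full forward for one raw sequence, with caches
model_fwd <- function(model, x, train = FALSE) {
  p <- model$params
  cfg <- model$config
  bb <- backbone_fwd(x, p$fe, cfg$backbone)
  n_scales <- length(bb$pyramid$scales)
  Ftil <- vector("list", n_scales)
  shc <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    lf <- linear_fwd(p$shared$W, p$shared$b, bb$pyramid$scales[[s]]$F)
    af <- prelu_fwd(lf$out, p$shared$slope)
    Ftil[[s]] <- af$out
    shc[[s]] <- list(l = lf$cache, a = af$cache)
  }
  ids <- vapply(bb$pyramid$scales, `[[`, numeric(1), "i")
  enc <- encode_fwd(Ftil, ids, p$tse, cfg$encoder, train = train)
  list(H = enc$H,
       cache = list(bb = bb$cache, shared = shc, enc = enc$caches,
                    n_scales = n_scales))
}

# backward from gradients at the encoder outputs; returns grads for
# fe / shared / tse
model_bwd <- function(model, cache, dH) {
  p <- model$params
  cfg <- model$config
  eb <- encode_bwd(dH, cache$enc, p$tse)
  g_shared <- tree_zeros(p$shared)
  dF <- vector("list", cache$n_scales)
  for (s in seq_len(cache$n_scales)) {
    ab <- prelu_bwd(eb$dF[[s]], cache$shared[[s]]$a)
    lb <- linear_bwd(ab$dX, cache$shared[[s]]$l)
    g_shared$W <- g_shared$W + lb$dW
    g_shared$b <- g_shared$b + lb$db
    g_shared$slope <- g_shared$slope + ab$dslope
    dF[[s]] <- lb$dX
  }
  g_fe <- backbone_bwd(dF, cache$bb, p$fe, cfg$backbone)
  list(fe = g_fe, shared = g_shared, tse = eb$grads)
}

#' Predict stages for a batch of raw sequences
#'
#' @param model a trained [sleep_model()].
#' @param X matrix with one `3000 * L`-sample sequence per row (or a single
#'   vector).
#' @return list with `stages` (factor), `logits` (n x 5 matrix of fused
#'   logits), `per_scale` (list of per-scale logit matrices).
#' @export
predict_stages <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n <- nrow(X)
  fused <- matrix(0, n, 5, dimnames = list(NULL, SLEEP_STAGES))
  idx <- integer(n)
  for (b in seq_len(n)) {
    fwd <- model_fwd(model, X[b, ], train = FALSE)
    cl <- as2c_fwd(fwd$H, model$params$as2c)
    fp <- fuse_predict(cl$logits)
    fused[b, ] <- fp$fused
    idx[b] <- fp$index
  }
  list(stages = factor(SLEEP_STAGES[idx], levels = SLEEP_STAGES),
       logits = fused)
}

# multi-scale cross-entropy (sum of per-scale CE against the target label)
ce_loss_grad <- function(logits_list, y_idx) {
  loss <- 0
  dlogits <- vector("list", length(logits_list))
  for (s in seq_along(logits_list)) {
    o <- logits_list[[s]]
    pr <- softmax_vec(o)
    loss <- loss - log(max(pr[y_idx], 1e-300))
    d <- pr
    d[y_idx] <- d[y_idx] - 1
    dlogits[[s]] <- d
  }
  list(loss = loss, dlogits = dlogits)
}

#' Save model weights to a checkpoint file
#'
#' Stores the named parameter groups (`fe`, `shared`, `tse`, `projector`,
#' `as2c`) with a configuration fingerprint so incompatible loads are
#' refused.
#'
#' @param model a [sleep_model()].
#' @param path destination file.
#' @param meta optional list of extra metadata (training history etc.).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, meta = NULL) {
  fp <- config_fingerprint(model$config)
  saveRDS(list(params = model$params, config = model$config,
               fingerprint = fp, meta = meta), path)
  invisible(path)
}

#' Load model weights from a checkpoint file
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param expect_config optional [model_config()]; loading fails when the
#'   checkpoint's configuration fingerprint differs.
#' @return a [sleep_model()] (attribute `meta` carries stored metadata).
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!is.null(expect_config) &&
      !identical(config_fingerprint(expect_config), ck$fingerprint)) {
    stop("checkpoint configuration fingerprint does not match the model")
  }
  m <- structure(list(params = ck$params, config = ck$config),
                 class = "sleep_model")
  attr(m, "meta") <- ck$meta
  m
}

config_fingerprint <- function(config) {
  paste(deparse(config), collapse = "")
}
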