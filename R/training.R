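#' Training configuration
#'
#' AdamW with the standard staging hyperparameters: learning rate 1e-4,
#' epsilon 1e-8, betas 0.9/0.999, no weight decay; contrastive batches of
#' 128 sequences and classification batches of 1024; validation every 400
#' (contrastive) / 50 (classification) iterations; early stopping after 20
#' consecutive evaluations without improvement.
#'
#' @param lr learning rate.
#' @param eps,beta1,beta2 AdamW moment parameters.
#' @param weight_decay decoupled weight decay (default 0).
#' @param scl_batch contrastive batch size N_b.
#' @param ce_batch classification batch size.
#' @param scl_validation_interval,ce_validation_interval iterations between
#'   validation evaluations per phase.
#' @param patience consecutive non-improving evaluations before stopping.
#' @param max_iterations hard iteration cap per phase (default `Inf`; set a
#'   finite cap for small desk-scale runs).
#' @param freeze_encoder freeze feature extractor + encoder during
#'   fine-tuning (default TRUE).
#' @param tau Supcon temperature.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, eps = 1e-8, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0, scl_batch = 128, ce_batch = 1024,
                         scl_validation_interval = 400,
                         ce_validation_interval = 50, patience = 20,
                         max_iterations = Inf, freeze_encoder = TRUE,
                         tau = 0.07) {
  stopifnot(lr > 0, patience >= 1, scl_batch >= 1, ce_batch >= 1, tau > 0)
  structure(list(lr = lr, eps = eps, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, scl_batch = scl_batch,
                 ce_batch = ce_batch,
                 scl_validation_interval = scl_validation_interval,
                 ce_validation_interval = ce_validation_interval,
                 patience = patience, max_iterations = max_iterations,
                 freeze_encoder = freeze_encoder, tau = tau),
            class = "train_config")
}

# --- AdamW on parameter trees ----------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0)
}

adamw_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + cfg$eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - cfg$lr * u, params, upd)
  if (cfg$weight_decay > 0) {
    params <- tree_map(function(p) p * (1 - cfg$lr * cfg$weight_decay), params)
  }
  list(params = params, state = state)
}

#' Early-stopping monitor
#'
#' Tracks the best (minimum) validation loss; signals a stop exactly after
#' `patience` consecutive non-improving evaluations. The counter resets on
#' every strict improvement.
#'
#' @param patience number of consecutive non-improving evaluations tolerated.
#' @return environment of class `early_stopper` with fields `best`,
#'   `best_eval`, `count`, `n_evals`; update it with [early_stopper_update()].
#' @export
make_early_stopper <- function(patience = 20) {
  stopifnot(patience >= 1)
  e <- new.env()
  e$patience <- patience
  e$best <- Inf
  e$best_eval <- 0L
  e$count <- 0L
  e$n_evals <- 0L
  class(e) <- "early_stopper"
  e
}

#' Feed one validation loss to an early stopper
#'
#' @param es an [make_early_stopper()] object (updated in place).
#' @param loss new validation loss.
#' @return list with `improved` and `stop` (logical).
#' @export
early_stopper_update <- function(es, loss) {
  es$n_evals <- es$n_evals + 1L
  improved <- loss < es$best
  if (improved) {
    es$best <- loss
    es$best_eval <- es$n_evals
    es$count <- 0L
  } else {
    es$count <- es$count + 1L
  }
  list(improved = improved, stop = es$count >= es$patience)
}

# forward all views of a multiview batch, returning per-scale projection
# matrices plus the per-view caches needed for backprop
scl_forward <- function(model, X, train = TRUE) {
  n <- nrow(X)
  n_scales <- length(model$config$backbone$reductions)
  d_proj <- nrow(model$params$projector$W2)
  Z <- lapply(seq_len(n_scales), function(s) matrix(0, d_proj, n))
  caches <- vector("list", n)
  for (b in seq_len(n)) {
    fwd <- model_fwd(model, X[b, ], train = train)
    pc <- vector("list", n_scales)
    for (s in seq_len(n_scales)) {
      pf <- projector_fwd(fwd$H[[s]], model$params$projector)
      Z[[s]][, b] <- pf$z
      pc[[s]] <- pf$cache
    }
    caches[[b]] <- list(model = fwd$cache, proj = pc)
  }
  list(Z = Z, caches = caches)
}

# Supcon loss + full gradients for one multiview batch
scl_loss_grads <- function(model, X, labels, tau, train = TRUE) {
  fw <- scl_forward(model, X, train = train)
  n_scales <- length(fw$Z)
  loss <- 0
  dZ <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    sg <- supcon_grad(fw$Z[[s]], labels, tau)
    loss <- loss + sg$loss
    dZ[[s]] <- sg$dZ
  }
  grads <- list(fe = tree_zeros(model$params$fe),
                shared = tree_zeros(model$params$shared),
                tse = tree_zeros(model$params$tse),
                projector = tree_zeros(model$params$projector))
  for (b in seq_len(nrow(X))) {
    dH <- vector("list", n_scales)
    for (s in seq_len(n_scales)) {
      pb <- projector_bwd(dZ[[s]][, b], fw$caches[[b]]$proj[[s]],
                          model$params$projector)
      grads$projector <- tree_add(grads$projector, pb$grads)
      dH[[s]] <- pb$dH
    }
    mb <- model_bwd(model, fw$caches[[b]]$model, dH)
    grads$fe <- tree_add(grads$fe, mb$fe)
    grads$shared <- tree_add(grads$shared, mb$shared)
    grads$tse <- tree_add(grads$tse, mb$tse)
  }
  list(loss = loss, grads = grads)
}

# validation Supcon loss on a fixed multiview batch (no dropout)
scl_eval_loss <- function(model, views, tau) {
  fw <- scl_forward(model, views$X, train = FALSE)
  sum(vapply(fw$Z, supcon_loss, numeric(1), labels = views$labels, tau = tau))
}

#' Phase 1: supervised contrastive pre-training
#'
#' Trains the feature extractor, encoder and projector by minimizing the
#' multi-scale Supcon loss over augmented multiview batches; the classifier
#' (AS2C) is untouched. Validation Supcon loss is monitored on a fixed
#' multiview batch built from the validation split; the parameters from the
#' best evaluation are returned.
#'
#' @param model a [sleep_model()].
#' @param train_seqs,val_seqs `eeg_sequences` splits (see
#'   [make_sequences_all()]); both must be nonempty.
#' @param config a [train_config()].
#' @param aug an [augment_config()].
#' @param seed integer seed driving batching, augmentation and dropout.
#' @param verbose print one line per evaluation.
#' @return the model with the best-validation parameters; attribute
#'   `history` holds a data frame of (iteration, train_loss, val_loss).
#' @export
pretrain_scl <- function(model, train_seqs, val_seqs, config = train_config(),
                         aug = augment_config(), seed = 1, verbose = FALSE) {
  if (nrow(train_seqs$X) == 0 || nrow(val_seqs$X) == 0) {
    stop("training and validation splits must be nonempty")
  }
  groups <- c("fe", "shared", "tse", "projector")
  opt <- adamw_init(model$params[groups])
  n_val <- min(nrow(val_seqs$X), config$scl_batch)
  val_sub <- list(X = val_seqs$X[seq_len(n_val), , drop = FALSE],
                  labels = val_seqs$labels[seq_len(n_val)])
  val_views <- make_two_views(structure(val_sub, class = "eeg_sequences"),
                              aug, seed = substream_seed(seed, 999331))
  es <- make_early_stopper(config$patience)
  best_params <- model$params
  hist <- list()
  it <- 0
  n_train <- nrow(train_seqs$X)
  repeat {
    it <- it + 1
    iseed <- substream_seed(seed, it)
    old <- .Random.seed_save()
    set.seed(iseed)
    idx <- sample.int(n_train, min(config$scl_batch, n_train))
    batch <- structure(list(X = train_seqs$X[idx, , drop = FALSE],
                            labels = train_seqs$labels[idx]),
                       class = "eeg_sequences")
    views <- make_two_views(batch, aug, seed = substream_seed(iseed, 5))
    set.seed(substream_seed(iseed, 6)) # dropout stream
    sg <- suppressWarnings(
      scl_loss_grads(model, views$X, views$labels, config$tau, train = TRUE))
    .Random.seed_restore(old)
    st <- adamw_step(model$params[groups], sg$grads, opt, config)
    model$params[groups] <- st$params
    opt <- st$state
    stop_now <- FALSE
    if (it %% config$scl_validation_interval == 0) {
      vl <- suppressWarnings(scl_eval_loss(model, val_views, config$tau))
      up <- early_stopper_update(es, vl)
      if (up$improved) best_params <- model$params
      hist[[length(hist) + 1]] <- data.frame(iteration = it,
                                             train_loss = sg$loss,
                                             val_loss = vl)
      if (verbose) {
        message(sprintf("[scl] iter %d train %.4f val %.4f%s", it, sg$loss,
                        vl, if (up$improved) " *" else ""))
      }
      stop_now <- up$stop
    }
    if (stop_now || it >= config$max_iterations) break
  }
  model$params <- best_params
  attr(model, "history") <- do.call(rbind, hist)
  attr(model, "best_val") <- es$best
  model
}

# CE loss over cached encoder outputs (frozen path)
ce_eval_loss_cached <- function(model, H_cache, y_idx) {
  tot <- 0
  for (b in seq_along(H_cache)) {
    cl <- as2c_fwd(H_cache[[b]], model$params$as2c)
    tot <- tot + ce_loss_grad(cl$logits, y_idx[b])$loss
  }
  tot / length(H_cache)
}

#' Phase 2: fine-tune the classifier with the encoder frozen
#'
#' Minimizes the multi-scale cross-entropy (summed over pyramid scales)
#' w.r.t. the AS2C parameters. With `config$freeze_encoder` (the default)
#' the feature extractor and encoder are bitwise untouched and their outputs
#' are precomputed once; with the flag off, gradients flow through the whole
#' network (the full-fine-tuning ablation).
#'
#' @inheritParams pretrain_scl
#' @param checkpoint optional path of a phase-1 checkpoint to load into
#'   `model` before training (an error if missing).
#' @return the model with best-validation parameters; attribute `history`
#'   as in [pretrain_scl()].
#' @export
finetune <- function(model, train_seqs, val_seqs, config = train_config(),
                     seed = 1, checkpoint = NULL, verbose = FALSE) {
  if (!is.null(checkpoint)) {
    model <- load_checkpoint(checkpoint, expect_config = model$config)
  }
  if (nrow(train_seqs$X) == 0 || nrow(val_seqs$X) == 0) {
    stop("training and validation splits must be nonempty")
  }
  freeze <- isTRUE(config$freeze_encoder)
  groups <- if (freeze) "as2c" else c("fe", "shared", "tse", "as2c")
  trainable <- function(pl) {
    out <- pl[groups]
    out$as2c <- out$as2c[c("Ws", "bs", "u", "Wa", "ba")]
    out
  }
  put_back <- function(model, upd) {
    for (g in groups) {
      if (g == "as2c") model$params$as2c[names(upd$as2c)] <- upd$as2c
      else model$params[[g]] <- upd[[g]]
    }
    model
  }
  opt <- adamw_init(trainable(model$params))
  y_train <- as.integer(train_seqs$labels)
  y_val <- as.integer(val_seqs$labels)

  cache_H <- function(seqs) {
    lapply(seq_len(nrow(seqs$X)), function(b) {
      model_fwd(model, seqs$X[b, ], train = FALSE)$H
    })
  }
  if (freeze) {
    H_train <- cache_H(train_seqs)
    H_val <- cache_H(val_seqs)
  }

  es <- make_early_stopper(config$patience)
  best_params <- model$params
  hist <- list()
  it <- 0
  n_train <- nrow(train_seqs$X)
  repeat {
    it <- it + 1
    old <- .Random.seed_save()
    set.seed(substream_seed(seed, 40000 + it))
    idx <- sample.int(n_train, min(config$ce_batch, n_train))
    .Random.seed_restore(old)
    grads <- tree_zeros(trainable(model$params))
    loss <- 0
    for (b in idx) {
      if (freeze) {
        H <- H_train[[b]]
        cl <- as2c_fwd(H, model$params$as2c)
        ce <- ce_loss_grad(cl$logits, y_train[b])
        ab <- as2c_bwd(ce$dlogits, cl, model$params$as2c)
        grads$as2c <- tree_add(grads$as2c, ab$grads)
      } else {
        fwd <- model_fwd(model, train_seqs$X[b, ], train = FALSE)
        cl <- as2c_fwd(fwd$H, model$params$as2c)
        ce <- ce_loss_grad(cl$logits, y_train[b])
        ab <- as2c_bwd(ce$dlogits, cl, model$params$as2c)
        grads$as2c <- tree_add(grads$as2c, ab$grads)
        mb <- model_bwd(model, fwd$cache, ab$dH)
        grads$fe <- tree_add(grads$fe, mb$fe)
        grads$shared <- tree_add(grads$shared, mb$shared)
        grads$tse <- tree_add(grads$tse, mb$tse)
      }
      loss <- loss + ce$loss
    }
    st <- adamw_step(trainable(model$params), grads, opt, config)
    model$params <- put_back(model, st$params)$params
    opt <- st$state
    stop_now <- FALSE
    if (it %% config$ce_validation_interval == 0) {
      vl <- if (freeze) ce_eval_loss_cached(model, H_val, y_val) else {
        tot <- 0
        for (b in seq_along(y_val)) {
          fwd <- model_fwd(model, val_seqs$X[b, ], train = FALSE)
          cl <- as2c_fwd(fwd$H, model$params$as2c)
          tot <- tot + ce_loss_grad(cl$logits, y_val[b])$loss
        }
        tot / length(y_val)
      }
      up <- early_stopper_update(es, vl)
      if (up$improved) best_params <- model$params
      hist[[length(hist) + 1]] <- data.frame(iteration = it,
                                             train_loss = loss / length(idx),
                                             val_loss = vl)
      if (verbose) {
        message(sprintf("[ce] iter %d train %.4f val %.4f%s", it,
                        loss / length(idx), vl, if (up$improved) " *" else ""))
      }
      stop_now <- up$stop
    }
    if (stop_now || it >= config$max_iterations) break
  }
  model$params <- best_params
  attr(model, "history") <- do.call(rbind, hist)
  attr(model, "best_val") <- es$best
  model
}

#' Evaluate a model on a sequence set
#'
#' @param model a [sleep_model()].
#' @param seqs an `eeg_sequences` object.
#' @return a [metrics_report()]; attribute `predictions` holds the predicted
#'   stages.
#' @export
evaluate_model <- function(model, seqs) {
  pr <- predict_stages(model, seqs$X)
  rep <- metrics_report(seqs$labels, pr$stages)
  attr(rep, "predictions") <- pr$stages
  rep
}

#' Split a sequence set into train and validation parts
#'
#' Stratified by stage label so small validation splits keep all classes.
#'
#' @param seqs an `eeg_sequences` object.
#' @param val_fraction fraction held out for validation.
#' @param seed integer seed.
#' @return list with `train` and `val` `eeg_sequences`.
#' @export
split_sequences <- function(seqs, val_fraction = 0.2, seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 77))
  n <- nrow(seqs$X)
  val_idx <- integer(0)
  for (st in levels(seqs$labels)) {
    cls <- which(seqs$labels == st)
    if (length(cls) == 0) next
    k <- max(1, round(length(cls) * val_fraction))
    val_idx <- c(val_idx, sample(cls, min(k, length(cls))))
  }
  val_idx <- sort(unique(val_idx))
  tr_idx <- setdiff(seq_len(n), val_idx)
  subset_seq <- function(i) structure(list(X = seqs$X[i, , drop = FALSE],
                                           labels = seqs$labels[i], L = seqs$L),
                                      class = "eeg_sequences")
  list(train = subset_seq(tr_idx), val = subset_seq(val_idx))
}
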