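#' Default run configuration
#'
#' Nested configuration covering all components; every key can be overridden
#' from a YAML file. Defaults: 6 encoder layers, d_f = 128, 8 heads, max
#' pooling with stride 6, temperature 0.07, learning rate 1e-4.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = ".",
    data = list(profile = "synthetic", subjects = 4, epochs = 120, L = 10,
                class_weights = c(0.350, 0.108, 0.347, 0.065, 0.130)),
    backbone = list(mode = "pyramid", d_f = 128, d_fe = 128,
                    base_reduction = 25, R = 5),
    encoder = list(num_layers = 6, heads = 8, ffnn_ratio = 1,
                   pool_mode = "max", pool_stride = 6, dropout = 0.1,
                   layernorm = TRUE),
    classifier = list(mean_pool = FALSE),
    augment = list(amplitude_shift = c(-10, 10), amplitude_scale = c(0.5, 2),
                   time_shift = c(-300, 300), zero_mask_len = c(0, 300),
                   bandstop_low = c(0.5, 30), bandstop_width = 2,
                   noise_sigma = c(0, 0.2), per_transform_probability = 0.5),
    contrastive = list(batch_size = 128, temperature = 0.07, d_proj = 128),
    training = list(lr = 1e-4, eps = 1e-8, beta1 = 0.9, beta2 = 0.999,
                    weight_decay = 0, ce_batch = 1024,
                    scl_validation_interval = 400,
                    ce_validation_interval = 50, patience = 20,
                    max_iterations = Inf, freeze_encoder = TRUE,
                    val_fraction = 0.2),
    flops = list(L = 1200, d = 128, r = 1, n = 6)
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(base)) stop("unknown configuration key: ", key)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) stop("key ", key, " must be a mapping")
      base[[k]] <- merge_config(base[[k]], override[[k]], key)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # constructors perform the range validation
  backbone_config(mode = cfg$backbone$mode, d_f = cfg$backbone$d_f,
                  d_fe = cfg$backbone$d_fe,
                  base_reduction = cfg$backbone$base_reduction,
                  R = cfg$backbone$R)
  encoder_config(num_layers = cfg$encoder$num_layers, d_f = cfg$backbone$d_f,
                 heads = cfg$encoder$heads, ffnn_ratio = cfg$encoder$ffnn_ratio,
                 pool_mode = cfg$encoder$pool_mode,
                 pool_stride = cfg$encoder$pool_stride,
                 R = cfg$backbone$R, dropout = cfg$encoder$dropout,
                 layernorm = cfg$encoder$layernorm)
  do.call(augment_config, cfg$augment)
  if (cfg$contrastive$temperature <= 0) stop("temperature must be positive")
  if (cfg$training$lr <= 0) stop("learning rate must be positive")
  if (cfg$data$L < 1) stop("data.L must be >= 1")
  invisible(cfg)
}

#' Parse a YAML configuration file
#'
#' Reads the file, overlays it on [default_config()], rejects unknown keys
#' and validates invariants. An empty file yields the defaults.
#'
#' @param path YAML file (or `NULL` for pure defaults).
#' @return validated nested configuration list.
#' @export
parse_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    override <- yaml::read_yaml(path)
    if (!is.null(override)) cfg <- merge_config(cfg, override)
  }
  validate_config(cfg)
}

#' Serialize a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_to_objects <- function(cfg) {
  bb <- backbone_config(mode = cfg$backbone$mode, d_f = cfg$backbone$d_f,
                        d_fe = cfg$backbone$d_fe,
                        base_reduction = cfg$backbone$base_reduction,
                        R = cfg$backbone$R)
  enc <- encoder_config(num_layers = cfg$encoder$num_layers,
                        d_f = cfg$backbone$d_f, heads = cfg$encoder$heads,
                        ffnn_ratio = cfg$encoder$ffnn_ratio,
                        pool_mode = cfg$encoder$pool_mode,
                        pool_stride = cfg$encoder$pool_stride,
                        R = cfg$backbone$R, dropout = cfg$encoder$dropout,
                        layernorm = cfg$encoder$layernorm)
  list(
    model = model_config(backbone = bb, encoder = enc, L = cfg$data$L,
                         d_proj = cfg$contrastive$d_proj),
    augment = do.call(augment_config, cfg$augment),
    train = train_config(lr = cfg$training$lr, eps = cfg$training$eps,
                         beta1 = cfg$training$beta1, beta2 = cfg$training$beta2,
                         weight_decay = cfg$training$weight_decay,
                         scl_batch = cfg$contrastive$batch_size,
                         ce_batch = cfg$training$ce_batch,
                         scl_validation_interval = cfg$training$scl_validation_interval,
                         ce_validation_interval = cfg$training$ce_validation_interval,
                         patience = cfg$training$patience,
                         max_iterations = cfg$training$max_iterations,
                         freeze_encoder = cfg$training$freeze_encoder,
                         tau = cfg$contrastive$temperature)
  )
}

load_dataset_dir <- function(dir, channel = "EEG Fpz-Cz") {
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  if (length(files) == 0) stop("no EDF files found in ", dir)
  lapply(files, function(f) {
    rec <- read_recording(f, channel)
    h <- harmonize_labels(rec$raw_labels)
    spe <- round(rec$fs * 30)
    n_ep <- length(rec$signal) %/% spe
    ep <- matrix(rec$signal[seq_len(n_ep * spe)], nrow = n_ep, byrow = TRUE)
    eeg_recording(ep[h$keep, , drop = FALSE], h$labels,
                  sampling_rate = rec$fs,
                  subject_id = sub("\\.edf$", "", basename(f)))
  })
}

cli_usage <- function() {
  paste(
    "usage: maxsleep <command> [--config FILE] [--seed N] [--out DIR]",
    "                [--data DIR] [--checkpoint FILE]",
    "commands: simulate | pretrain | finetune | evaluate | flops | augment-preview",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(config = NULL, seed = NULL, out = ".", data = NULL,
               checkpoint = NULL)
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts)) stop("unknown option: ", argv[i])
    if (i + 1 > length(argv)) stop("missing value for --", key)
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (!is.null(opts$seed)) opts$seed <- as.integer(opts$seed)
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `maxsleep` script: `simulate` writes a seeded
#' synthetic dataset (EDF + label sidecars), `pretrain` / `finetune` /
#' `evaluate` run the two-phase training pipeline on a dataset directory,
#' `flops` prints the analytic cost model, and `augment-preview` writes
#' before/after traces of the augmentation pipeline.
#'
#' @param argv character vector of command-line arguments (command first).
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv) {
  if (length(argv) < 1) {
    message(cli_usage())
    return(invisible(1L))
  }
  command <- argv[1]
  commands <- c("simulate", "pretrain", "finetune", "evaluate", "flops",
                "augment-preview")
  if (!command %in% commands) {
    message("unknown command: ", command, "\n", cli_usage())
    return(invisible(1L))
  }
  opts <- parse_cli_args(argv[-1])
  cfg <- parse_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  out <- opts$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(out, "resolved-config.yaml"))
  obj <- config_to_objects(cfg)

  if (command == "flops") {
    fl <- cfg$flops
    std <- forward_flops("standard", fl$L, fl$d, fl$r)
    mx <- forward_flops("max", fl$L, fl$d, fl$r, fl$n)
    res <- list(standard = unclass(std), max = unclass(mx),
                reduction_percent = flops_reduction(fl$L, fl$d, fl$r, fl$n))
    js <- jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA)
    writeLines(js, file.path(out, "flops.json"))
    print(std); print(mx)
    cat(sprintf("reduction: %.1f%%\n", res$reduction_percent))
    return(invisible(0L))
  }

  if (command == "simulate") {
    recs <- generate_dataset(cfg$data$subjects, cfg$data$epochs,
                             class_weights = cfg$data$class_weights,
                             seed = cfg$seed)
    for (r in recs) {
      write_recording(r, file.path(out, paste0(r$subject_id, ".edf")))
    }
    message(sprintf("wrote %d recordings to %s", length(recs), out))
    return(invisible(0L))
  }

  if (command == "augment-preview") {
    spec <- default_stage_specs()$N2
    x <- synthesize_epoch(spec, seed = cfg$seed)
    x <- (x - mean(x)) / stats::sd(x)
    y <- augment_pipeline(x, obj$augment, seed = cfg$seed)
    utils::write.csv(data.frame(sample = seq_along(x), before = x,
                                after = as.numeric(y)),
                     file.path(out, "augment-preview.csv"), row.names = FALSE)
    message("applied transforms: ",
            paste(names(which(attr(y, "applied"))), collapse = ", "))
    return(invisible(0L))
  }

  # training-family commands need data
  if (is.null(opts$data)) stop(command, " requires --data DIR")
  profile <- dataset_profile(cfg$data$profile)
  recs <- load_dataset_dir(opts$data, profile$channel)
  seqs <- make_sequences_all(recs, cfg$data$L)
  sp <- split_sequences(seqs, cfg$training$val_fraction, cfg$seed)

  if (command == "pretrain") {
    model <- sleep_model(obj$model, seed = cfg$seed)
    model <- pretrain_scl(model, sp$train, sp$val, obj$train, obj$augment,
                          seed = cfg$seed, verbose = TRUE)
    save_checkpoint(model, file.path(out, "pretrained.rds"),
                    meta = list(phase = "scl", history = attr(model, "history")))
    return(invisible(0L))
  }
  if (command == "finetune") {
    if (is.null(opts$checkpoint)) stop("finetune requires --checkpoint FILE")
    model <- sleep_model(obj$model, seed = cfg$seed)
    model <- finetune(model, sp$train, sp$val, obj$train, seed = cfg$seed,
                      checkpoint = opts$checkpoint, verbose = TRUE)
    save_checkpoint(model, file.path(out, "finetuned.rds"),
                    meta = list(phase = "ce", history = attr(model, "history")))
    return(invisible(0L))
  }
  if (command == "evaluate") {
    if (is.null(opts$checkpoint)) stop("evaluate requires --checkpoint FILE")
    model <- load_checkpoint(opts$checkpoint)
    rep <- evaluate_model(model, seqs)
    print(rep)
    write_metrics_json(rep, file.path(out, "metrics.json"))
    pred <- attr(rep, "predictions")
    utils::write.csv(data.frame(epoch = seq_along(pred),
                                reference = seqs$labels, predicted = pred),
                     file.path(out, "predictions.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(rep$confusion),
                     file.path(out, "confusion.csv"))
    return(invisible(0L))
  }
  invisible(1L)
}
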