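# Training protocol: MSE loss, Adam, random crops of normalized pairs.
# Scratch training, fine-tuning under a freeze policy (frozen parameters are
# never touched, so they stay bit-identical), and direct-transfer
# evaluation (pure inference on a foreign test set).

#' Training configuration
#'
#' Mirrors the published protocol: MSE loss, Adam (0.9/0.999), learning
#' rate 1e-4, 100 epochs from scratch and 30 for fine-tuning, random square
#' crops. Desk-scale runs in this package's own experiments use fewer, see
#' the vignette.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Images per optimizer step.
#' @param crop_size Random crop side (multiple of 32), or `NULL` for full
#'   images.
#' @param seed Integer seed for shuffling and cropping.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         batch_size = 1L, crop_size = 256L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  if (!is.null(crop_size)) stopifnot(crop_size %% 32L == 0L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 crop_size = if (is.null(crop_size)) NULL else
                   as.integer(crop_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(names) {
  list(t = 0L, m = stats::setNames(vector("list", length(names)), names),
       v = stats::setNames(vector("list", length(names)), names))
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

# cache of loaded pairs, keyed by input path
preload_pairs <- function(manifest) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) out[[i]] <- load_pair(manifest[i, ])
  out
}

random_crop_pair <- function(pair, crop) {
  H <- nrow(pair$input); W <- ncol(pair$input)
  if (is.null(crop) || (crop >= H && crop >= W)) {
    return(pair)
  }
  ch <- min(crop, H); cw <- min(crop, W)
  r0 <- sample.int(H - ch + 1L, 1L) - 1L
  c0 <- sample.int(W - cw + 1L, 1L) - 1L
  list(input = pair$input[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE],
       reference = pair$reference[r0 + seq_len(ch), c0 + seq_len(cw),
                                  drop = FALSE])
}

img_to_col <- function(img) matrix(as.vector(t(img)), ncol = 1L)

#' Train a model on a pair manifest
#'
#' Iterates `config$epochs` epochs over randomly ordered, randomly cropped
#' (input, reference) pairs, minimizing the mean squared error between the
#' model output and the reference on the normalized intensity scale. Only
#' parameters marked trainable are updated, so the same routine serves
#' scratch training (all trainable) and fine-tuning (after
#' [apply_freeze_policy()]). Deterministic given the seed.
#'
#' @param model A `sim_model`.
#' @param manifest A non-empty `dataset_manifest` with valid file paths.
#' @param config A [train_config()].
#' @param strategy Label stored in the run (`"scratch"` or `"finetune"`).
#' @return A `train_run`: list with the trained `model`, per-epoch mean
#'   `history`, `n_steps`, `strategy` and the config.
#' @export
train <- function(model, manifest, config = train_config(),
                  strategy = "scratch") {
  if (nrow(manifest) == 0L) stop("empty training manifest")
  pairs <- preload_pairs(manifest)
  trainable_names <- names(model$params)[model$trainable]
  opt <- adam_init(trainable_names)
  history <- numeric(config$epochs)
  n_steps <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        take <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        i <- i + length(take)
        grads <- NULL
        batch_loss <- 0
        for (j in take) {
          pr <- random_crop_pair(pairs[[j]], config$crop_size)
          tape <- ag_tape()
          x <- ag_const(tape, img_to_col(pr$input))
          fw <- model_forward(model, x, nrow(pr$input), ncol(pr$input), tape)
          loss <- ag_mse(fw$out, img_to_col(pr$reference), tape)
          ag_backward(tape, loss)
          batch_loss <- batch_loss + loss$value
          if (!is.finite(loss$value)) stop("non-finite training loss")
          g <- lapply(fw$leaves[trainable_names], function(nd) nd$grad)
          null_g <- vapply(g, is.null, logical(1))
          g[null_g] <- lapply(model$params[trainable_names][null_g],
                              function(p) p * 0)
          grads <- if (is.null(grads)) g else mapply(`+`, grads, g,
                                                     SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, function(g) g / length(take))
        upd <- adam_step(opt, model$params, grads, config$learning_rate)
        opt <- upd$opt
        model$params <- upd$params
        n_steps <- n_steps + 1L
        losses <- c(losses, batch_loss / length(take))
      }
      history[ep] <- mean(losses)
    }
  })
  structure(list(model = model, history = history, n_steps = n_steps,
                 strategy = strategy, config = config),
            class = "train_run")
}

#' Fine-tune a pretrained model under its freeze policy
#'
#' Applies [apply_freeze_policy()] for the model's architecture before any
#' optimizer step, then trains for `config$epochs` (default 30) on the
#' target manifest. Frozen parameters are bit-identical to the checkpoint
#' afterwards.
#'
#' @param model A pretrained `sim_model`, or a checkpoint path.
#' @param manifest Target-domain training manifest.
#' @param config A [train_config()]; default epochs 30.
#' @export
finetune <- function(model, manifest, config = train_config(epochs = 30L)) {
  if (is.character(model)) model <- load_checkpoint(model)
  model <- apply_freeze_policy(model)
  train(model, manifest, config, strategy = "finetune")
}

#' Evaluate a pretrained model on a foreign test set (direct transfer)
#'
#' Pure inference: no parameter is updated. Returns the metric report of
#' the model's outputs on the other domain's test manifest.
#'
#' @param model A pretrained `sim_model`, or a checkpoint path.
#' @param test_manifest Test manifest of the other dataset.
#' @export
direct_transfer_eval <- function(model, test_manifest) {
  if (is.character(model)) model <- load_checkpoint(model)
  evaluate_model(model, test_manifest)
}
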