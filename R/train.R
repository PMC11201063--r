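# ---------------------------------------------------------------------------
# Training, evaluation and prediction pipeline: Adam with weight decay,
# polynomial learning-rate schedule, per-epoch logging, best-checkpoint
# tracking.
# ---------------------------------------------------------------------------

#' Polynomial learning-rate schedule
#'
#' `lr = init_lr * (1 - epoch / max_epoch)^power`. Monotone non-increasing
#' in the epoch; exactly `init_lr` at epoch 0 and exactly 0 at
#' `epoch = max_epoch`.
#'
#' @param init_lr initial learning rate
#' @param epoch current epoch (0-based)
#' @param max_epoch total number of epochs
#' @param power decay exponent
#' @return the learning rate
#' @export
poly_lr <- function(init_lr, epoch, max_epoch, power = 0.9) {
  if (epoch < 0 || epoch > max_epoch)
    stop("epoch must lie in [0, max_epoch]")
  init_lr * (1 - epoch / max_epoch)^power
}

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, initial learning rate
#' 0.001, poly decay with power 0.9 over 200 epochs, weight decay 1e-5,
#' batch size 8.
#'
#' @param init_lr initial learning rate
#' @param power poly schedule exponent
#' @param max_epoch number of epochs
#' @param batch_size samples per optimizer step
#' @param weight_decay L2 coefficient added to the gradients (Adam)
#' @param sigma Dice smoothing constant of the loss
#' @param bce_reduction `"mean"` or `"sum"` for the BCE term
#' @param seed seed for shuffling (and any run-level randomness)
#' @param shuffle reshuffle the training set every epoch
#' @param augment apply random flip/rotation augmentation each epoch
#' @param log_path optional JSON-lines file receiving one record per epoch
#' @return a `lcf_train_config` list
#' @export
train_config <- function(init_lr = 0.001, power = 0.9, max_epoch = 200,
                         batch_size = 8, weight_decay = 1e-5, sigma = 1,
                         bce_reduction = "mean", seed = 1L, shuffle = TRUE,
                         augment = FALSE, log_path = NULL) {
  stopifnot(init_lr > 0, power > 0, max_epoch >= 1, batch_size >= 1)
  cfg <- list(init_lr = init_lr, power = power,
              max_epoch = as.integer(max_epoch),
              batch_size = as.integer(batch_size),
              weight_decay = weight_decay, sigma = sigma,
              bce_reduction = bce_reduction, seed = as.integer(seed),
              shuffle = isTRUE(shuffle), augment = isTRUE(augment),
              log_path = log_path)
  class(cfg) <- c("lcf_train_config", "list")
  cfg
}

# ---- Adam optimizer ------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$wd <- weight_decay
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(st, lr = NULL) {
  if (!is.null(lr)) st$lr <- lr
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + st$wd * p$value
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / c1) /
      (sqrt(st$v[[i]] / c2) + st$eps)
    p$grad <- NULL
  }
  invisible(st)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- training loop -------------------------------------------------------

#' Train a segmentation model
#'
#' Runs the standard loop: seeded shuffling into mini-batches, forward pass
#' with batch statistics, compound BCE-Dice loss, backpropagation and an
#' Adam step with the poly learning rate of the current epoch. One epoch
#' record (epoch, learning rate, mean training loss, optional validation
#' IoU/DSC) is logged per epoch; the weights achieving the best validation
#' DSC are kept when validation data is given.
#'
#' @param model an `lcf_model` from [build_model()]
#' @param data list of `lcf_sample` training pairs (identical sizes)
#' @param cfg a [train_config()] list
#' @param val_data optional list of `lcf_sample` validation pairs
#' @param max_steps optional cap on the total number of optimizer steps
#' @return list with `model`, `log` (data.frame), `best_dsc`,
#'   `best_weights` (named list of arrays, NULL without validation data)
#' @export
train <- function(model, data, cfg = train_config(), val_data = NULL,
                  max_steps = NULL) {
  stopifnot(inherits(model, "lcf_model"), inherits(cfg, "lcf_train_config"))
  if (!length(data)) stop("empty dataset")
  params <- module_params(model$module)
  opt <- adam_new(params, lr = cfg$init_lr, weight_decay = cfg$weight_decay)
  n <- length(data)
  log <- list()
  best_dsc <- -Inf
  best_weights <- NULL
  steps_done <- 0L
  set.seed(cfg$seed)
  if (!is.null(cfg$log_path) && file.exists(cfg$log_path))
    unlink(cfg$log_path)
  for (epoch in seq_len(cfg$max_epoch) - 1L) {
    lr <- poly_lr(cfg$init_lr, epoch, cfg$max_epoch, cfg$power)
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    losses <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      if (!is.null(max_steps) && steps_done >= max_steps) break
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      batch <- data[idx]
      if (cfg$augment) batch <- lapply(batch, augment)
      tb <- samples_to_tensors(batch)
      ctx <- list(training = TRUE)
      pred <- model_forward_node(model, as_node(tb$x), ctx)
      loss <- bce_dice_loss_node(pred, as_node(tb$y), sigma = cfg$sigma,
                                 bce_reduction = cfg$bce_reduction)
      if (!is.finite(loss$value))
        stop(sprintf(
          "NaN/Inf loss at epoch %d step %d; aborting (check learning rate and inputs)",
          epoch, steps_done + 1L))
      zero_grads(params)
      tp_backward(loss)
      adam_step(opt, lr = lr)
      losses <- c(losses, loss$value)
      steps_done <- steps_done + 1L
    }
    rec <- list(epoch = epoch, lr = lr,
                train_loss = if (length(losses)) mean(losses) else NA_real_,
                steps = steps_done)
    if (!is.null(val_data)) {
      vm <- evaluate(model, val_data)
      rec$val_iou <- vm$iou
      rec$val_dsc <- vm$dsc
      if (vm$dsc > best_dsc) {
        best_dsc <- vm$dsc
        best_weights <- lapply(params, function(p) p$value)
      }
    }
    log[[length(log) + 1L]] <- rec
    if (!is.null(cfg$log_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = cfg$log_path, append = TRUE)
    if (!is.null(max_steps) && steps_done >= max_steps) break
  }
  logdf <- do.call(rbind, lapply(log, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(model = model, log = logdf,
       best_dsc = if (is.finite(best_dsc)) best_dsc else NA_real_,
       best_weights = best_weights, steps = steps_done)
}

#' Evaluate a model on a set of image/mask pairs
#'
#' Deterministic eval-mode inference; per-image confusion metrics at
#' threshold 0.5, averaged across images; AUC pooled over all pixels.
#'
#' @param model an `lcf_model`
#' @param data list of `lcf_sample` pairs
#' @param threshold binarisation threshold on the probability map
#' @param with_auc compute the pooled pixel AUC (skipped if the ground
#'   truth has a single class)
#' @return an `lcf_metrics` report
#' @export
evaluate <- function(model, data, threshold = 0.5, with_auc = FALSE) {
  if (!length(data)) stop("empty dataset")
  rows <- list()
  all_p <- c(); all_g <- c()
  for (s in data) {
    tb <- samples_to_tensors(list(s))
    p <- model_forward(model, tb$x)
    pb <- (p >= threshold) * 1
    r <- confusion_metrics(pb, tb$y)
    r$id <- s$id
    rows[[length(rows) + 1L]] <- r
    if (with_auc) {
      all_p <- c(all_p, as.numeric(p))
      all_g <- c(all_g, as.numeric(tb$y))
    }
  }
  per <- do.call(rbind, rows)
  auc <- NA_real_
  if (with_auc && length(unique(all_g)) == 2)
    auc <- roc_auc(all_p, all_g)
  metrics_report(per, auc)
}

#' Predict binary masks for images
#'
#' @param model an `lcf_model`
#' @param images list of `lcf_sample` objects, or a (B, 3, H, W) array
#' @param threshold binarisation threshold
#' @param out_dir optional directory; predicted masks are written as PNG
#'   files with values 0/255
#' @param ids file basenames when writing (defaults to sample ids)
#' @return list of binary mask matrices
#' @export
predict_masks <- function(model, images, threshold = 0.5, out_dir = NULL,
                          ids = NULL) {
  if (is.list(images) && !is.array(images)) {
    if (is.null(ids)) ids <- vapply(images, function(s) s$id, character(1))
    x <- samples_to_tensors(images)$x
  } else {
    x <- images
    if (is.null(ids)) ids <- sprintf("pred_%03d", seq_len(dim(x)[1]))
  }
  p <- model_forward(model, x)
  B <- dim(p)[1]
  masks <- lapply(seq_len(B), function(i) {
    m <- (p[i, 1, , ] >= threshold) * 1L
    matrix(m, dim(p)[3], dim(p)[4])
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(B))
      png::writePNG(masks[[i]] + 0,
                    file.path(out_dir, paste0(ids[i], ".png")))
  }
  names(masks) <- ids
  masks
}

#' Profile a model configuration
#'
#' Builds the model and reports the exact count of trainable scalars,
#' total and per top-level component.
#'
#' @param cfg a [model_config()] list
#' @param seed build seed (the count does not depend on it)
#' @return list with `params` (total), `params_m` (millions) and
#'   `by_component` (named numeric vector)
#' @export
profile_model <- function(cfg = model_config(), seed = 42L) {
  m <- build_model(cfg, seed)
  by_comp <- vapply(m$children, count_parameters, numeric(1))
  list(variant = cfg$variant,
       params = count_parameters(m),
       params_m = count_parameters(m) / 1e6,
       by_component = by_comp)
}
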