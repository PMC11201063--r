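# ---------------------------------------------------------------------------
# LightCF-Net assembly: five encoder stages (residual block then four fusion
# attention stages), Mamba-attention skip connections, pyramid split
# attention bottleneck, four decoder blocks and a 1x1 sigmoid head.
# ---------------------------------------------------------------------------

MODEL_VARIANTS <- c("baseline", "faencoder_no_ca", "faencoder", "vam",
                    "faencoder_vam", "full")

#' Model configuration
#'
#' @param variant one of `"baseline"` (plain U-Net), `"faencoder_no_ca"`,
#'   `"faencoder"`, `"vam"`, `"faencoder_vam"`, `"full"` — the ablation
#'   ladder of the architecture
#' @param stage_channels five encoder stage widths (default
#'   `c(16, 32, 64, 128, 128)`)
#' @param decoder_channels four decoder stage widths, deepest first
#'   (default `c(64, 64, 32, 16)`; the deepest decoder halves the
#'   bottleneck width, the rest mirror the encoder)
#' @param in_channels input image channels (3 for RGB)
#' @param out_channels output channels (1, binary foreground probability)
#' @param lka [lka_config()] list
#' @param faencoder list with `hidden_ratio`
#' @param vam [vam_config()] list
#' @param psa [psa_config()] list
#' @param attention list with `ca_reduction` and `sa_kernel`
#' @return a `lcf_config` list
#' @export
model_config <- function(variant = "full",
                         stage_channels = c(16L, 32L, 64L, 128L, 128L),
                         decoder_channels = c(64L, 64L, 32L, 16L),
                         in_channels = 3L, out_channels = 1L,
                         lka = lka_config(),
                         faencoder = list(hidden_ratio = 1),
                         vam = vam_config(),
                         psa = psa_config(),
                         attention = list(ca_reduction = 4, sa_kernel = 7)) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(length(stage_channels) == 5, length(decoder_channels) == 4,
            all(stage_channels >= 1), all(decoder_channels >= 1))
  cfg <- list(variant = variant,
              stage_channels = as.integer(stage_channels),
              decoder_channels = as.integer(decoder_channels),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              lka = lka, faencoder = faencoder, vam = vam, psa = psa,
              attention = attention)
  class(cfg) <- c("lcf_config", "list")
  cfg
}

#' Read a model configuration from a YAML file
#' @param path YAML file; keys mirror the [model_config()] arguments
#' @return a `lcf_config` list
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("variant", "stage_channels", "decoder_channels",
              "in_channels", "out_channels"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$lka))
    args$lka <- do.call(lka_config, y$lka[names(y$lka) != "erf"])
  if (!is.null(y$vam)) args$vam <- do.call(vam_config, y$vam)
  if (!is.null(y$psa)) args$psa <- do.call(psa_config, y$psa)
  if (!is.null(y$faencoder)) args$faencoder <- y$faencoder
  if (!is.null(y$attention)) args$attention <- y$attention
  do.call(model_config, args)
}

#' Write a model configuration to YAML
#' @param cfg a `lcf_config` list
#' @param path output file
#' @export
write_model_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$vam$levels <- as.integer(y$vam$levels)
  yaml::write_yaml(y, path)
}

uses_faencoder <- function(variant)
  variant %in% c("faencoder_no_ca", "faencoder", "faencoder_vam", "full")
uses_vam <- function(variant)
  variant %in% c("vam", "faencoder_vam", "full")
uses_psa <- function(variant) variant == "full"

#' Build a segmentation model
#'
#' Encoder stage 1 is a residual block at full resolution; stages 2-5 each
#' apply a 2x2 max-pool followed by either a fusion attention encoder or a
#' residual block, depending on the variant. Variants with VAM attach a
#' Mamba-attention module to each of the four skip connections; the `full`
#' variant adds pyramid split attention after the bottleneck stage. Four
#' decoder blocks mirror the encoder and a 1x1 convolution with sigmoid
#' yields the foreground probability map.
#'
#' @param cfg a [model_config()] list
#' @param seed integer seed for weight initialisation; the same
#'   configuration and seed give bitwise-identical weights
#' @return an object of class `lcf_model`
#' @export
build_model <- function(cfg = model_config(), seed = 42L) {
  stopifnot(inherits(cfg, "lcf_config"))
  sc <- cfg$stage_channels
  dc <- cfg$decoder_channels
  car <- cfg$attention$ca_reduction
  sak <- cfg$attention$sa_kernel
  with_seed(seed, {
    enc <- list()
    enc[[1]] <- new_residual_block(cfg$in_channels, sc[1])
    for (i in 2:5) {
      enc[[i]] <- if (uses_faencoder(cfg$variant))
        new_faencoder(sc[i - 1], sc[i], lka = cfg$lka,
                      hidden_ratio = cfg$faencoder$hidden_ratio,
                      use_ca = cfg$variant != "faencoder_no_ca",
                      ca_reduction = car)
      else new_residual_block(sc[i - 1], sc[i])
    }
    vams <- NULL
    if (uses_vam(cfg$variant)) {
      vams <- lapply(cfg$vam$levels, function(i)
        new_vam(sc[i], cfg$vam, ca_reduction = car, sa_kernel = sak))
      names(vams) <- paste0("vam", cfg$vam$levels)
    }
    psa <- if (uses_psa(cfg$variant)) new_psa(sc[5], cfg$psa) else NULL
    dec <- list(
      new_decoder_block(sc[5], sc[4], dc[1]),
      new_decoder_block(dc[1], sc[3], dc[2]),
      new_decoder_block(dc[2], sc[2], dc[3]),
      new_decoder_block(dc[3], sc[1], dc[4]))
    head <- layer_conv2d(dc[4], cfg$out_channels, 1, bias = TRUE)
    children <- stats::setNames(enc, paste0("enc", 1:5))
    if (!is.null(vams)) children <- c(children, vams)
    if (!is.null(psa)) children <- c(children, list(psa = psa))
    children <- c(children, stats::setNames(dec, paste0("dec", 4:1)),
                  list(head = head))
    root <- new_module("lightcf", children = children)
    m <- list(config = cfg, seed = as.integer(seed), module = root,
              children = children)
    class(m) <- "lcf_model"
    m
  })
}

#' @export
print.lcf_model <- function(x, ...) {
  cat(sprintf("LightCF-Net model, variant '%s'\n", x$config$variant))
  cat(sprintf("  stage channels: {%s}\n",
              paste(x$config$stage_channels, collapse = ", ")))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

# forward pass on the tape; x is a node, returns the probability-map node
model_forward_node <- function(m, x, ctx) {
  cfg <- m$config
  ch <- m$children
  skips <- vector("list", 4)
  h <- ch$enc1$fwd(x, ctx)
  skips[[1]] <- h
  for (i in 2:5) {
    h <- ch[[paste0("enc", i)]]$fwd(tp_maxpool2(h), ctx)
    if (i < 5) skips[[i]] <- h
  }
  if (!is.null(ch$psa)) h <- ch$psa$fwd(h, ctx)
  if (uses_vam(cfg$variant)) {
    for (i in cfg$vam$levels) {
      v <- ch[[paste0("vam", i)]]
      if (!is.null(v)) skips[[i]] <- v$fwd(skips[[i]], ctx)
    }
  }
  h <- ch$dec4$fwd(h, skips[[4]], ctx)
  h <- ch$dec3$fwd(h, skips[[3]], ctx)
  h <- ch$dec2$fwd(h, skips[[2]], ctx)
  h <- ch$dec1$fwd(h, skips[[1]], ctx)
  tp_sigmoid(ch$head$fwd(h, ctx))
}

#' Forward inference
#'
#' @param m an `lcf_model`
#' @param images (B, 3, H, W) array with H and W divisible by 16
#' @param training logical; TRUE uses batch statistics in batch norm
#' @return (B, 1, H, W) probability map with values in (0, 1)
#' @export
model_forward <- function(m, images, training = FALSE) {
  stopifnot(inherits(m, "lcf_model"))
  d <- dim(images)
  if (length(d) != 4 || d[2] != m$config$in_channels)
    stop(sprintf("shape error: expected (B, %d, H, W) input",
                 m$config$in_channels))
  if (d[3] %% 16 != 0 || d[4] %% 16 != 0)
    stop(sprintf(
      "shape error: spatial size %dx%d not divisible by 16 (required multiple: 16)",
      d[3], d[4]))
  # `training` only selects batch statistics in the normalisation layers;
  # inference never records gradients (the training loop drives the tape
  # through model_forward_node directly)
  ctx <- list(training = isTRUE(training))
  without_grad(model_forward_node(m, as_node(images), ctx)$value)
}

#' Count trainable parameters
#' @param m an `lcf_model` or any module
#' @return integer count of trainable scalars
#' @export
count_parameters <- function(m) {
  mod <- if (inherits(m, "lcf_model")) m$module else m
  ps <- module_params(mod)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

#' Save model weights and configuration
#'
#' The checkpoint stores the flat named parameter list, the batch-norm
#' running statistics, and the YAML text of the configuration that built
#' the model, so it is self-describing.
#'
#' @param m an `lcf_model`
#' @param path output file (RDS)
#' @param extra optional named list stored alongside (e.g. training log)
#' @export
save_checkpoint <- function(m, path, extra = list()) {
  ps <- module_params(m$module)
  weights <- lapply(ps, function(p) p$value)
  buffers <- collect_buffers(m$module)
  cfgy <- yaml::as.yaml(unclass(m$config))
  saveRDS(list(config_yaml = cfgy, seed = m$seed, weights = weights,
               buffers = buffers, extra = extra), path)
  invisible(path)
}

collect_buffers <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$buffers))
    out[[prefix]] <- list(running_mean = m$buffers$running_mean,
                          running_var = m$buffers$running_var)
  for (nm in names(m$children))
    out <- c(out, collect_buffers(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

restore_buffers <- function(m, buffers, prefix = "") {
  if (!is.null(m$buffers) && !is.null(buffers[[prefix]])) {
    m$buffers$running_mean <- buffers[[prefix]]$running_mean
    m$buffers$running_var <- buffers[[prefix]]$running_var
  }
  for (nm in names(m$children))
    restore_buffers(m$children[[nm]], buffers, paste0(prefix, nm, "."))
  invisible(NULL)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()]
#' @return an `lcf_model` with restored weights and running statistics
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, config_args_from_yaml(ck$config_yaml))
  m <- build_model(cfg, seed = ck$seed)
  ps <- module_params(m$module)
  missing <- setdiff(names(ck$weights), names(ps))
  extra_keys <- setdiff(names(ps), names(ck$weights))
  if (length(missing) || length(extra_keys))
    stop(sprintf("checkpoint/config mismatch; differing keys: %s",
                 paste(c(missing, extra_keys), collapse = ", ")))
  for (nm in names(ps)) ps[[nm]]$value <- ck$weights[[nm]]
  restore_buffers(m$module, ck$buffers)
  m$checkpoint_extra <- ck$extra
  m
}

config_args_from_yaml <- function(txt) {
  y <- yaml::yaml.load(txt)
  args <- list()
  for (k in c("variant", "stage_channels", "decoder_channels",
              "in_channels", "out_channels"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$lka)) args$lka <- do.call(lka_config, y$lka[names(y$lka) != "erf"])
  if (!is.null(y$vam)) args$vam <- do.call(vam_config, y$vam)
  if (!is.null(y$psa))
    args$psa <- psa_config(y$psa$splits, y$psa$groups, y$psa$se_reduction)
  if (!is.null(y$faencoder)) args$faencoder <- y$faencoder
  if (!is.null(y$attention)) args$attention <- y$attention
  args
}
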