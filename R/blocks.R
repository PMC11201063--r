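# ---------------------------------------------------------------------------
# Shared building blocks: residual conv block, channel attention, spatial
# attention, squeeze-excitation weights and the decoder block.
# ---------------------------------------------------------------------------

#' Channel attention (squeeze-and-excitation gate)
#'
#' Global average pooling followed by a two-layer bottleneck MLP and a
#' sigmoid produces one gate in (0, 1) per channel; the input is rescaled
#' channel-wise. The bottleneck width is `max(4, floor(channels/reduction))`,
#' so narrow stages (16 channels) keep a non-degenerate hidden layer.
#'
#' @param channels number of input channels
#' @param reduction bottleneck reduction ratio (default 4)
#' @return a module; apply with [module_apply()]
#' @export
new_channel_attention <- function(channels, reduction = 4) {
  if (channels < 1) stop("invalid config: channel count must be >= 1")
  hid <- max(4L, channels %/% reduction)
  fc1 <- layer_linear(channels, hid)
  fc2 <- layer_linear(hid, channels)
  children <- list(fc1 = fc1, fc2 = fc2)
  new_module("channel_attention", children = children,
             fwd = function(x, ctx) {
               g <- tp_gap(x)
               g <- tp_dense(g, fc1$params$w, fc1$params$b)
               g <- tp_relu(g)
               g <- tp_dense(g, fc2$params$w, fc2$params$b)
               g <- tp_sigmoid(g)
               tp_scale_ch(x, g)
             },
             meta = list(channels = channels, reduction = reduction,
                         hidden = hid))
}

#' Spatial attention gate
#'
#' Per-pixel channel mean and max are stacked into a two-channel map,
#' convolved with a `kernel` x `kernel` filter and squashed by a sigmoid,
#' yielding a single-channel spatial gate in (0, 1) that rescales the input.
#'
#' @param kernel odd convolution kernel size (default 7)
#' @return a module
#' @export
new_spatial_attention <- function(kernel = 7) {
  conv <- layer_conv2d(2, 1, kernel, bias = TRUE)
  new_module("spatial_attention", children = list(conv = conv),
             fwd = function(x, ctx) {
               s <- tp_concat_ch(list(tp_chmean(x), tp_chmax(x)))
               s <- conv$fwd(s, ctx)
               s <- tp_sigmoid(s)
               tp_scale_sp(x, s)
             },
             meta = list(kernel = kernel))
}

#' Squeeze-excitation channel descriptor (pre-softmax logits)
#'
#' Global average pooling followed by the two-layer bottleneck MLP, without
#' the final sigmoid: returns one logit per channel, as consumed by the
#' pyramid split attention softmax.
#'
#' @param channels input channel count
#' @param reduction bottleneck reduction ratio
#' @return a module whose output is a (batch x channels) matrix of logits
#' @export
new_se_weight <- function(channels, reduction = 4) {
  hid <- max(4L, channels %/% reduction)
  fc1 <- layer_linear(channels, hid)
  fc2 <- layer_linear(hid, channels)
  new_module("se_weight", children = list(fc1 = fc1, fc2 = fc2),
             fwd = function(x, ctx) {
               g <- tp_gap(x)
               g <- tp_dense(g, fc1$params$w, fc1$params$b)
               g <- tp_relu(g)
               tp_dense(g, fc2$params$w, fc2$params$b)
             },
             meta = list(channels = channels, reduction = reduction))
}

#' Residual convolution block
#'
#' Two 3x3 conv / batch-norm / ReLU layers with an identity shortcut
#' (1x1 projection + batch norm when the channel count changes).
#'
#' @param cin,cout input and output channel counts
#' @return a module
#' @export
new_residual_block <- function(cin, cout) {
  conv1 <- layer_conv2d(cin, cout, 3, bias = FALSE)
  bn1 <- layer_bn2d(cout)
  conv2 <- layer_conv2d(cout, cout, 3, bias = FALSE)
  bn2 <- layer_bn2d(cout)
  children <- list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2)
  proj <- NULL
  if (cin != cout) {
    proj <- layer_conv2d(cin, cout, 1, bias = FALSE)
    bnp <- layer_bn2d(cout)
    children$proj <- proj
    children$bnp <- bnp
  }
  new_module("residual_block", children = children,
             fwd = function(x, ctx) {
               h <- tp_relu(bn1$fwd(conv1$fwd(x, ctx), ctx))
               h <- bn2$fwd(conv2$fwd(h, ctx), ctx)
               s <- if (is.null(proj)) x
                    else children$bnp$fwd(proj$fwd(x, ctx), ctx)
               tp_relu(tp_add(h, s))
             },
             meta = list(cin = cin, cout = cout))
}

#' Decoder block
#'
#' Bilinear 2x upsampling of the deep feature map, channel concatenation
#' with the skip feature, then two 3x3 conv/batch-norm/ReLU layers with a
#' 1x1 residual projection. The skip map must have exactly twice the spatial
#' size of the deep input.
#'
#' @param cin_x channels of the deep input
#' @param cin_skip channels of the skip input
#' @param cout output channels
#' @return a module; apply as `module_apply(m, x, skip)`
#' @export
new_decoder_block <- function(cin_x, cin_skip, cout) {
  cin <- cin_x + cin_skip
  conv1 <- layer_conv2d(cin, cout, 3, bias = FALSE)
  bn1 <- layer_bn2d(cout)
  conv2 <- layer_conv2d(cout, cout, 3, bias = FALSE)
  bn2 <- layer_bn2d(cout)
  proj <- layer_conv2d(cin, cout, 1, bias = FALSE)
  bnp <- layer_bn2d(cout)
  children <- list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2,
                   proj = proj, bnp = bnp)
  new_module("decoder_block", children = children,
             fwd = function(x, skip, ctx) {
               dx <- dim(nv(x)); ds <- dim(nv(skip))
               if (ds[3] != 2 * dx[3] || ds[4] != 2 * dx[4])
                 stop("decoder block: skip spatial size must be twice the input")
               u <- tp_upsample2(x)
               cc <- tp_concat_ch(list(u, skip))
               h <- tp_relu(bn1$fwd(conv1$fwd(cc, ctx), ctx))
               h <- bn2$fwd(conv2$fwd(h, ctx), ctx)
               s <- bnp$fwd(proj$fwd(cc, ctx), ctx)
               tp_relu(tp_add(h, s))
             },
             meta = list(cin_x = cin_x, cin_skip = cin_skip, cout = cout))
}

#' Set every trainable parameter of a module to a constant
#'
#' Mainly useful in tests and worked examples where deterministic weights
#' are needed (e.g. zeroed convolutions make a residual block the identity).
#'
#' @param m module
#' @param value constant (default 0); batch-norm scale parameters are set to
#'   1 when `keep_bn_scale` is TRUE
#' @param keep_bn_scale keep gamma = 1 in batch-norm layers
#' @return the module, invisibly (parameters are environments, modified in
#'   place)
#' @export
module_fill <- function(m, value = 0, keep_bn_scale = TRUE) {
  ps <- module_params(m)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (keep_bn_scale && grepl("\\.gamma$", nm)) {
      p$value[] <- 1
    } else {
      p$value[] <- value
    }
  }
  invisible(m)
}
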