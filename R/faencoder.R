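# ---------------------------------------------------------------------------
# Fusion Attention Encoder: Large Kernel Attention decomposition fused with a
# pointwise branch and channel attention.
# ---------------------------------------------------------------------------

#' Default Large Kernel Attention decomposition settings
#'
#' A 21x21 effective receptive field decomposed into a 5x5 depth-wise
#' convolution, a 7x7 depth-wise convolution with dilation 3, and a 1x1
#' pointwise convolution.
#'
#' @param dw_kernel depth-wise kernel size (odd)
#' @param dwd_kernel dilated depth-wise kernel size (odd)
#' @param dwd_dilation dilation of the second convolution
#' @return list with the three settings and the implied effective receptive
#'   field `erf = dw_kernel + (dwd_kernel - 1) * dwd_dilation`
#' @export
lka_config <- function(dw_kernel = 5, dwd_kernel = 7, dwd_dilation = 3) {
  if (dw_kernel %% 2 == 0 || dwd_kernel %% 2 == 0)
    stop("invalid config: LKA kernel sizes must be odd")
  if (dwd_dilation < 1) stop("invalid config: dilation must be positive")
  list(dw_kernel = as.integer(dw_kernel),
       dwd_kernel = as.integer(dwd_kernel),
       dwd_dilation = as.integer(dwd_dilation),
       erf = as.integer(dw_kernel + (dwd_kernel - 1) * dwd_dilation))
}

#' Large Kernel Attention block
#'
#' Computes `Attention = Conv1x1(DWDConv(DWConv(x)))` and returns the
#' elementwise product `Attention * x`. All three convolutions preserve the
#' spatial size; the depth-wise convolutions act per channel. The
#' convolutions carry biases and no normalisation, so fixing them to delta
#' kernels makes the attention chain the identity.
#'
#' @param channels channel count
#' @param cfg an [lka_config()] list
#' @return a module
#' @export
new_lka <- function(channels, cfg = lka_config()) {
  dw <- layer_conv2d(channels, channels, cfg$dw_kernel,
                     groups = channels, bias = TRUE)
  dwd <- layer_conv2d(channels, channels, cfg$dwd_kernel,
                      dilation = cfg$dwd_dilation, groups = channels,
                      bias = TRUE)
  pw <- layer_conv2d(channels, channels, 1, bias = TRUE)
  new_module("lka", children = list(dw = dw, dwd = dwd, pw = pw),
             fwd = function(x, ctx) {
               att <- pw$fwd(dwd$fwd(dw$fwd(x, ctx), ctx), ctx)
               tp_mul(att, x)
             },
             meta = c(cfg, list(channels = channels)))
}

#' Fusion Attention Encoder stage
#'
#' The input passes a 3x3 convolution to `cout` channels (X2). Branch one
#' applies 1x1 conv, GELU, Large Kernel Attention and a second 1x1 conv;
#' branch two is a plain 1x1 conv. The branches are added, fused by a 3x3
#' convolution and recalibrated by channel attention.
#'
#' @param cin,cout input/output channel counts
#' @param lka an [lka_config()] list
#' @param hidden_ratio width multiplier of the attention branch (default 1,
#'   i.e. the branch runs at `cout` channels)
#' @param use_ca include the channel-attention gate (disabled in the
#'   `faencoder_no_ca` ablation variant)
#' @param ca_reduction channel-attention reduction ratio
#' @return a module
#' @export
new_faencoder <- function(cin, cout, lka = lka_config(), hidden_ratio = 1,
                          use_ca = TRUE, ca_reduction = 4) {
  hid <- as.integer(round(cout * hidden_ratio))
  conv_in <- layer_conv2d(cin, cout, 3, bias = FALSE)
  bn_in <- layer_bn2d(cout)
  pw1 <- layer_conv2d(cout, hid, 1, bias = TRUE)
  lka_m <- new_lka(hid, lka)
  pw2 <- layer_conv2d(hid, cout, 1, bias = TRUE)
  pw_skip <- layer_conv2d(cout, cout, 1, bias = TRUE)
  fuse <- layer_conv2d(cout, cout, 3, bias = FALSE)
  bn_fuse <- layer_bn2d(cout)
  children <- list(conv_in = conv_in, bn_in = bn_in, pw1 = pw1, lka = lka_m,
                   pw2 = pw2, pw_skip = pw_skip, fuse = fuse,
                   bn_fuse = bn_fuse)
  if (use_ca) children$ca <- new_channel_attention(cout, ca_reduction)
  new_module("faencoder", children = children,
             fwd = function(x, ctx) {
               x2 <- tp_relu(bn_in$fwd(conv_in$fwd(x, ctx), ctx))
               y1 <- pw2$fwd(lka_m$fwd(tp_gelu(pw1$fwd(x2, ctx)), ctx), ctx)
               y2 <- pw_skip$fwd(x2, ctx)
               h <- tp_relu(bn_fuse$fwd(fuse$fwd(tp_add(y1, y2), ctx), ctx))
               if (use_ca) children$ca$fwd(h, ctx) else h
             },
             meta = list(cin = cin, cout = cout, hidden = hid,
                         use_ca = use_ca))
}
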