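# ---------------------------------------------------------------------------
# Visual Attention Mamba skip-connection module: flatten to a sequence,
# gated Mamba block around a selective state-space scan, fusion with a 1x1
# branch, then channel and spatial attention.
# ---------------------------------------------------------------------------

#' Flatten a feature map to sequence features
#'
#' Raster order: row 0 left to right, then row 1, and so on. The sequence
#' length is `L = H * W`.
#'
#' @param x (B, C, H, W) array
#' @return (B, L, C) array
#' @export
flatten_to_sequence <- function(x) {
  stopifnot(length(dim(x)) == 4)
  without_grad(tp_to_sequence(x))$value
}

#' Reshape sequence features back to a feature map
#'
#' Exact inverse of [flatten_to_sequence()].
#'
#' @param w (B, L, C) array with `L = H * W`
#' @param H,W target spatial size
#' @return (B, C, H, W) array
#' @export
reshape_to_map <- function(w, H, W) {
  stopifnot(length(dim(w)) == 3)
  if (dim(w)[2] != H * W) stop("shape error: L must equal H*W")
  without_grad(tp_to_map(w, H, W))$value
}

#' Run a selective state-space scan on plain arrays
#'
#' Evaluates the causal recurrence
#' `h_t = exp(delta_t * A) * h_{t-1} + (delta_t * B_t) * u_t`,
#' `y_t = C_t . h_t + D * u_t`
#' independently per channel, with a state of dimension `N` and
#' input-dependent step size and projections.
#'
#' @param u input sequence, (B, L, D) array
#' @param delta positive step sizes, (B, L, D)
#' @param A state transition matrix, (D, N), typically negative
#' @param B_proj,C_proj input/output projections per step, (B, L, N)
#' @param D_skip skip gain per channel, length D
#' @return output sequence, (B, L, D)
#' @export
selective_scan <- function(u, delta, A, B_proj, C_proj, D_skip) {
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("invalid parameter: delta must be positive and finite")
  cpp_scan_fw(u, delta, A, B_proj, C_proj, D_skip)
}

#' Default Visual Attention Mamba settings
#'
#' @param expansion channel expansion factor lambda of the Mamba block
#' @param state_dim state dimension N of the scan
#' @param conv_kernel causal depth-wise 1-d convolution kernel size
#' @param dt_rank rank of the step-size projection; `NULL` means
#'   `ceiling(channels / 16)`
#' @param levels encoder levels (1-4) whose skip connections carry a VAM
#' @return settings list
#' @export
vam_config <- function(expansion = 2, state_dim = 16, conv_kernel = 4,
                       dt_rank = NULL, levels = 1:4) {
  list(expansion = expansion, state_dim = as.integer(state_dim),
       conv_kernel = as.integer(conv_kernel), dt_rank = dt_rank,
       levels = as.integer(levels))
}

#' Mamba block over sequence features
#'
#' Two branches at width `lambda * C`: branch one applies a causal
#' depth-wise 1-d convolution, SiLU, the selective state-space scan and
#' layer normalisation; branch two is `SiLU(Linear(w))`. The branches are
#' multiplied (gating) and a final linear layer restores C channels.
#'
#' The state matrix is initialised as `A = -(1..N)` per channel (stored as
#' `A_log`), the skip gain D at 1, and the step-size bias so that the
#' softplus step starts in roughly 0.001 to 0.1.
#'
#' @param C channel count of the incoming sequence
#' @param cfg a [vam_config()] list
#' @return a module operating on (B, L, C) arrays
#' @export
new_mamba_block <- function(C, cfg = vam_config()) {
  lam <- cfg$expansion
  D <- lam * C
  if (D != round(D)) stop("invalid config: expansion * C must be an integer")
  D <- as.integer(D)
  N <- cfg$state_dim
  R <- if (is.null(cfg$dt_rank)) as.integer(ceiling(C / 16)) else
    as.integer(cfg$dt_rank)
  in1 <- layer_linear(C, D)
  in2 <- layer_linear(C, D)
  conv <- layer_conv1d_dw(D, cfg$conv_kernel)
  x_proj <- layer_linear(D, R + 2L * N, bias = FALSE)
  dt_proj <- layer_linear(R, D)
  # step sizes start log-uniform in [0.001, 0.1]
  dt0 <- exp(runif(D, log(0.001), log(0.1)))
  dt_proj$params$b$value <- log(expm1(dt0))
  A_log <- new_param(matrix(rep(log(seq_len(N)), each = D), D, N))
  D_skip <- new_param(rep(1, D))
  ln <- layer_layernorm(D)
  out <- layer_linear(D, C)
  children <- list(in1 = in1, in2 = in2, conv = conv, x_proj = x_proj,
                   dt_proj = dt_proj, ln = ln, out = out)
  params <- list(A_log = A_log, D_skip = D_skip)
  new_module("mamba_block", params = params, children = children,
             fwd = function(w, ctx) {
               u <- tp_silu(conv$fwd(in1$fwd(w, ctx), ctx))
               xp <- x_proj$fwd(u, ctx)
               dt <- tp_slice3(xp, 1L, R)
               Bm <- tp_slice3(xp, R + 1L, R + N)
               Cm <- tp_slice3(xp, R + N + 1L, R + 2L * N)
               delta <- tp_softplus(dt_proj$fwd(dt, ctx))
               A <- tp_neg(tp_exp(A_log))
               z1 <- ln$fwd(tp_scan(u, delta, A, Bm, Cm, D_skip), ctx)
               z2 <- tp_silu(in2$fwd(w, ctx))
               out$fwd(tp_mul(z1, z2), ctx)
             },
             meta = list(C = C, D = D, N = N, dt_rank = R))
}

#' Visual Attention Mamba skip module
#'
#' Branch one flattens the feature map to a raster sequence, applies layer
#' normalisation and the Mamba block, and reshapes back. Branch two is a 1x1
#' convolution preserving the encoder features. The branches are channel-
#' concatenated, fused by a 1x1 convolution with batch norm, and optimised
#' by channel attention followed by spatial attention. Output shape equals
#' input shape.
#'
#' @param C channel count
#' @param cfg a [vam_config()] list
#' @param ca_reduction channel-attention reduction ratio
#' @param sa_kernel spatial-attention kernel size
#' @return a module
#' @export
new_vam <- function(C, cfg = vam_config(), ca_reduction = 4, sa_kernel = 7) {
  ln_pre <- layer_layernorm(C)
  mamba <- new_mamba_block(C, cfg)
  conv_skip <- layer_conv2d(C, C, 1, bias = TRUE)
  fuse <- layer_conv2d(2L * C, C, 1, bias = FALSE)
  bn_fuse <- layer_bn2d(C)
  ca <- new_channel_attention(C, ca_reduction)
  sa <- new_spatial_attention(sa_kernel)
  children <- list(ln_pre = ln_pre, mamba = mamba, conv_skip = conv_skip,
                   fuse = fuse, bn_fuse = bn_fuse, ca = ca, sa = sa)
  new_module("vam", children = children,
             fwd = function(x, ctx) {
               d <- dim(nv(x))
               w <- tp_to_sequence(x)
               w <- ln_pre$fwd(w, ctx)
               w <- mamba$fwd(w, ctx)
               wmap <- tp_to_map(w, d[3], d[4])
               x2 <- conv_skip$fwd(x, ctx)
               h <- tp_concat_ch(list(wmap, x2))
               h <- bn_fuse$fwd(fuse$fwd(h, ctx), ctx)
               sa$fwd(ca$fwd(h, ctx), ctx)
             },
             meta = list(C = C))
}
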