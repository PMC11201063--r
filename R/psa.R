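# ---------------------------------------------------------------------------
# Pyramid Split Attention bottleneck: multi-kernel group convolutions over S
# pyramid branches, squeeze-excitation logits and a softmax across branches.
# ---------------------------------------------------------------------------

#' Pyramid kernel sizes
#'
#' `K_i = 2*(i+1) + 1` for branches i = 0..S-1, i.e. 3, 5, 7, 9 for S = 4.
#'
#' @param S number of pyramid branches
#' @return integer vector of kernel sizes
#' @export
psa_kernel_sizes <- function(S = 4) {
  as.integer(2L * (seq_len(S)) + 1L)
}

#' Pyramid group counts by the printed rule
#'
#' `G_i = 2^((K_i - 1) / 2)`, i.e. 2, 4, 8, 16 for kernels 3, 5, 7, 9.
#' The shipped bottleneck calibration uses a single group for the 3x3
#' branch (groups 1, 4, 8, 16), following the reference implementation of
#' the pyramid-split design; see [psa_config()].
#'
#' @param S number of pyramid branches
#' @return integer vector of group counts
#' @export
psa_group_formula <- function(S = 4) {
  k <- psa_kernel_sizes(S)
  as.integer(2^((k - 1) / 2))
}

#' Pyramid Split Attention settings
#'
#' @param splits number of branches S
#' @param groups group counts per branch; default follows the reference
#'   implementation (`c(1, 4, 8, 16)` for S = 4: the formula of
#'   [psa_group_formula()] with the first branch ungrouped)
#' @param se_reduction squeeze-excitation reduction ratio
#' @return settings list
#' @export
psa_config <- function(splits = 4, groups = NULL, se_reduction = 4) {
  splits <- as.integer(splits)
  if (is.null(groups)) {
    groups <- psa_group_formula(splits)
    groups[1] <- 1L
  }
  if (length(groups) != splits) stop("invalid config: need one group count per split")
  list(splits = splits, groups = as.integer(groups),
       se_reduction = se_reduction)
}

#' Pyramid Split Attention module
#'
#' The C input channels feed S parallel branches. Branch i applies a
#' `K_i x K_i` group convolution (with `G_i` groups) producing `C/S`
#' channels, followed by batch norm, giving multi-scale maps `F_i`. A shared
#' squeeze-excitation module computes per-channel logits for each branch; a
#' softmax across the S branches (independently per channel slot) yields
#' attention weights summing to one, which rescale each `F_i`. The
#' recalibrated branches are concatenated back to C channels.
#'
#' @param C input channel count; must be divisible by `splits`
#' @param cfg a [psa_config()] list
#' @return a module
#' @export
new_psa <- function(C, cfg = psa_config()) {
  S <- cfg$splits
  if (C %% S != 0)
    stop("invalid config: channels must be divisible by the number of splits")
  Cs <- C %/% S
  ks <- psa_kernel_sizes(S)
  convs <- list()
  bns <- list()
  for (i in seq_len(S)) {
    g <- cfg$groups[i]
    if (C %% g != 0 || Cs %% g != 0)
      stop("invalid config: group count must divide both C and C/S")
    convs[[i]] <- layer_conv2d(C, Cs, ks[i], groups = g, bias = FALSE)
    bns[[i]] <- layer_bn2d(Cs)
  }
  se <- new_se_weight(Cs, cfg$se_reduction)
  children <- c(stats::setNames(convs, paste0("conv", seq_len(S))),
                stats::setNames(bns, paste0("bn", seq_len(S))),
                list(se = se))
  new_module("psa", children = children,
             fwd = function(x, ctx) {
               Fs <- lapply(seq_len(S), function(i)
                 bns[[i]]$fwd(convs[[i]]$fwd(x, ctx), ctx))
               logits <- lapply(Fs, function(f) se$fwd(f, ctx))
               att <- tp_softmax_branch(tp_stack_branch(logits))
               Ts <- lapply(seq_len(S), function(i)
                 tp_scale_ch(Fs[[i]], tp_take_branch(att, i)))
               tp_concat_ch(Ts)
             },
             meta = list(C = C, splits = S, kernels = ks,
                         groups = cfg$groups))
}

#' Multi-scale pyramid convolutions of the PSA module
#'
#' Convenience accessor running only the S branch convolutions of a built
#' PSA module, returning the list of multi-scale maps `F_i` (each with C/S
#' channels) before attention recalibration.
#'
#' @param psa a module built by [new_psa()]
#' @param x input array (B, C, H, W)
#' @param training logical, batch-norm mode
#' @return list of S arrays, each (B, C/S, H, W)
#' @export
psa_split_conv <- function(psa, x, training = FALSE) {
  stopifnot(psa$kind == "psa")
  S <- psa$meta$splits
  ctx <- list(training = training)
  without_grad(lapply(seq_len(S), function(i) {
    f <- psa$children[[paste0("bn", i)]]$fwd(
      psa$children[[paste0("conv", i)]]$fwd(as_node(x), ctx), ctx)
    f$value
  }))
}
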