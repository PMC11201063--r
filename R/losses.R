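# ---------------------------------------------------------------------------
# Compound BCE-Dice loss.
# ---------------------------------------------------------------------------

#' Compound BCE-Dice segmentation loss
#'
#' `loss = BCE(P, G) + 1 - (2 * sum(G*P) + sigma) / (sum(G) + sum(P) + sigma)`
#'
#' The binary cross-entropy term is averaged per pixel by default so that the
#' loss scale is resolution independent; `bce_reduction = "sum"` uses the
#' plain sum instead. Predictions are clamped to `[eps, 1 - eps]` before the
#' logarithms. The smoothed Dice complement is zero exactly when `P = G`
#' for a binary `P`.
#'
#' @param P probability map, values in (0, 1) (any array shape)
#' @param G binary ground-truth mask, same shape as `P`
#' @param sigma Dice smoothing constant (default 1)
#' @param bce_reduction `"mean"` (default) or `"sum"`
#' @param eps clamping constant for the logarithms
#' @return scalar loss value
#' @export
bce_dice_loss <- function(P, G, sigma = 1, bce_reduction = c("mean", "sum"),
                          eps = 1e-7) {
  bce_reduction <- match.arg(bce_reduction)
  if (length(P) != length(G))
    stop("shape mismatch between prediction and ground truth")
  if (!all(G %in% c(0, 1))) stop("ground truth must be binary")
  l <- bce_dice_loss_node(as_node(P), as_node(G), sigma, bce_reduction, eps)
  without_grad(l$value)
}

# tape version used inside the training loop; P, G are nodes
bce_dice_loss_node <- function(P, G, sigma = 1, bce_reduction = "mean",
                               eps = 1e-7) {
  Pc <- tp_clamp(P, eps, 1 - eps)
  Gv <- G
  one_m_G <- tp_cadd(tp_neg(Gv), 1)
  bce_terms <- tp_add(tp_mul(Gv, tp_log(Pc)),
                      tp_mul(one_m_G, tp_log(tp_cadd(tp_neg(Pc), 1))))
  bce <- if (bce_reduction == "mean") tp_neg(tp_mean(bce_terms))
         else tp_neg(tp_sum(bce_terms))
  inter <- tp_sum(tp_mul(Gv, P))
  denom <- tp_add(tp_sum(Gv), tp_sum(P))
  dice <- tp_div(tp_cadd(tp_cmul(inter, 2), sigma), tp_cadd(denom, sigma))
  tp_add(bce, tp_cadd(tp_neg(dice), 1))
}
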