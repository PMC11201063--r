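# ---------------------------------------------------------------------------
# Segmentation metrics: confusion-matrix scores, ROC curve and AUC.
# ---------------------------------------------------------------------------

#' Confusion-matrix segmentation metrics for one image
#'
#' Computes IoU, Dice (DSC), sensitivity (SE), specificity (SP) and pixel
#' accuracy (ACC) from a binarised prediction and ground truth:
#' `IoU = TP/(TP+FP+FN)`, `DSC = 2TP/(2TP+FP+FN)`, `SE = TP/(TP+FN)`,
#' `SP = TN/(TN+FP)`, `ACC = (TP+TN)/n`. All five are returned as
#' percentages in \[0, 100\]. When both masks are empty (TP+FP+FN = 0) the
#' overlap scores IoU and DSC are 100 by convention; SE is 100 when there
#' are no positives, SP is 100 when there are no negatives.
#'
#' @param pred binary predicted mask (array or vector of 0/1)
#' @param gt binary ground-truth mask, same shape
#' @return data.frame with one row: tp, fp, fn, tn, iou, dsc, se, sp, acc
#' @export
confusion_metrics <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("shape mismatch between pred and gt")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be binary")
  p <- as.numeric(pred); g <- as.numeric(gt)
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  tn <- sum(p == 0 & g == 0)
  n <- tp + fp + fn + tn
  iou <- if (tp + fp + fn == 0) 100 else 100 * tp / (tp + fp + fn)
  dsc <- if (tp + fp + fn == 0) 100 else 100 * 2 * tp / (2 * tp + fp + fn)
  se <- if (tp + fn == 0) 100 else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) 100 else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / n
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             iou = iou, dsc = dsc, se = se, sp = sp, acc = acc)
}

#' Area under the ROC curve for pixel scores
#'
#' AUC is the probability that a randomly chosen positive pixel receives a
#' higher score than a randomly chosen negative pixel, with ties counted
#' one half — the Mann-Whitney rank statistic, computed via average ranks.
#'
#' @param probs numeric scores (probability map), any shape
#' @param gt binary ground-truth labels, same length
#' @param curve logical; also return ROC curve points
#' @param n_thresholds number of thresholds for the exported curve
#' @return if `curve` is FALSE, the AUC as a fraction in \[0, 1\]; otherwise
#'   a list with `auc` and a data.frame `roc` of (threshold, fpr, tpr)
#' @export
roc_auc <- function(probs, gt, curve = FALSE, n_thresholds = 101) {
  if (length(probs) != length(gt)) stop("shape mismatch")
  g <- as.numeric(gt)
  if (!all(g %in% c(0, 1))) stop("ground truth must be binary")
  n1 <- as.numeric(sum(g == 1)); n0 <- as.numeric(sum(g == 0))
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: ground truth contains a single class")
  s <- as.numeric(probs)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (!curve) return(auc)
  th <- seq(1, 0, length.out = n_thresholds)
  roc <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(s >= t & g == 0) / n0, numeric(1)),
    tpr = vapply(th, function(t) sum(s >= t & g == 1) / n1, numeric(1)))
  list(auc = auc, roc = roc)
}

#' Aggregate per-image metrics into a report
#'
#' Per-image metrics are averaged (not pooled over a joint confusion
#' matrix), the dominant convention in the polyp-segmentation literature.
#' AUC is computed over all pixels of all images jointly when probability
#' maps are supplied.
#'
#' @param per_image data.frame of per-image rows from [confusion_metrics()]
#' @param auc optional AUC fraction to attach
#' @return list of class `lcf_metrics` with fields iou, dsc, se, sp, acc
#'   (percent), auc (fraction or NA) and n_images
#' @export
metrics_report <- function(per_image, auc = NA_real_) {
  agg <- list(iou = mean(per_image$iou), dsc = mean(per_image$dsc),
              se = mean(per_image$se), sp = mean(per_image$sp),
              acc = mean(per_image$acc), auc = auc,
              n_images = nrow(per_image))
  structure(c(agg, list(per_image = per_image)), class = "lcf_metrics")
}

#' @export
print.lcf_metrics <- function(x, ...) {
  cat(sprintf(
    "segmentation metrics over %d image(s):\n  IoU %.2f%%  DSC %.2f%%  SE %.2f%%  SP %.2f%%  ACC %.2f%%",
    x$n_images, x$iou, x$dsc, x$se, x$sp, x$acc))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report an `lcf_metrics` object
#' @param csv_path per-image CSV (plus an `aggregate` row); NULL to skip
#' @param json_path JSON summary; NULL to skip
#' @param roc optional ROC curve data.frame written next to the CSV
#' @param roc_path CSV path for the ROC points
#' @return invisibly, the report
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL,
                          roc = NULL, roc_path = NULL) {
  if (!is.null(csv_path)) {
    per <- report$per_image
    agg <- per[1, , drop = FALSE]
    for (cn in c("iou", "dsc", "se", "sp", "acc"))
      agg[[cn]] <- report[[cn]]
    for (cn in c("tp", "fp", "fn", "tn")) agg[[cn]] <- NA
    if ("id" %in% names(per)) agg$id <- "aggregate" else agg$id <- "aggregate"
    out <- rbind(cbind(id = if ("id" %in% names(per)) per$id else
                         as.character(seq_len(nrow(per))),
                       per[setdiff(names(per), "id")]),
                 cbind(id = "aggregate", agg[setdiff(names(agg), "id")]))
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(iou = report$iou, dsc = report$dsc, se = report$se,
           sp = report$sp, acc = report$acc, auc = report$auc,
           n_images = report$n_images),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(roc) && !is.null(roc_path))
    utils::write.csv(roc, roc_path, row.names = FALSE)
  invisible(report)
}
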