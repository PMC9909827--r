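#' Pixelwise confusion counts between two binary planes
#'
#' @param pred binary prediction plane (matrix of 0/1).
#' @param gt binary ground-truth plane, same dims.
#' @return list of class `confusion_counts` with TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("prediction and ground truth dims differ")
  p <- as.logical(pred); g <- as.logical(gt)
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' Overlap agreement metrics from confusion counts
#'
#' DSC = 2TP/(FP+2TP+FN), IOU = TP/(FP+TP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN). Degenerate 0/0 cases: when both masks are empty
#' (TP = FP = FN = 0) all four metrics are 1 (agreement on absence); when
#' only one side is empty the undefined metrics are 0.
#'
#' @param counts a [confusion_counts()] object or list with TP/FP/FN.
#' @return list of class `agreement_report` with dsc, iou, precision, recall.
#' @export
agreement <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  safe <- function(num, den) if (den == 0) {
    if (TP + FP + FN == 0) 1 else 0
  } else num / den
  structure(list(dsc = safe(2 * TP, FP + 2 * TP + FN),
                 iou = safe(TP, FP + TP + FN),
                 precision = safe(TP, TP + FP),
                 recall = safe(TP, TP + FN)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  IOU %.4f  precision %.4f  recall %.4f\n",
              x$dsc, x$iou, x$precision, x$recall))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as automatic - manual; limits of agreement are
#' mean difference +/- 1.96 sample standard deviations (n - 1 denominator).
#'
#' @param manual numeric vector of reference measurements.
#' @param automatic numeric vector of paired automatic measurements.
#' @return object of class `bland_altman`: mean_diff, sd_diff, loa_low,
#'   loa_high, and per-pair (average, difference) points.
#' @export
bland_altman <- function(manual, automatic) {
  if (length(manual) != length(automatic)) stop("unequal pair lengths")
  if (length(manual) < 2) stop("need at least 2 pairs")
  d <- automatic - manual
  m <- mean(d); s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 points = data.frame(average = (manual + automatic) / 2,
                                     difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f, 95%% limits [%.4f, %.4f] (n = %d)\n",
              x$mean_diff, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$points$average, x$points$difference, xlab = "average of methods",
       ylab = "difference (automatic - manual)", main = "Bland-Altman", ...)
  graphics::abline(h = x$mean_diff)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `r2`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- cor(x, y)
  list(r = r, r2 = r^2)
}

#' Per-image segmentation evaluation table
#'
#' Compares predicted and ground-truth 3-channel masks image by image and
#' reports DSC/IOU/precision/recall per tissue, plus mean and SD rows per
#' tissue (equal image weight).
#'
#' @param pred_masks list of (H, W, 3) binary arrays.
#' @param gt_masks matching list of ground-truth arrays.
#' @return data frame with columns image, tissue, dsc, iou, precision,
#'   recall; summary rows have image = "mean" / "sd".
#' @export
evaluate_masks <- function(pred_masks, gt_masks) {
  stopifnot(length(pred_masks) == length(gt_masks))
  tissues <- c("subq", "visceral", "muscle")
  rows <- list()
  for (i in seq_along(pred_masks)) {
    for (k in 1:3) {
      a <- agreement(confusion_counts(pred_masks[[i]][, , k],
                                      gt_masks[[i]][, , k]))
      rows[[length(rows) + 1L]] <- data.frame(
        image = as.character(i), tissue = tissues[k], dsc = a$dsc,
        iou = a$iou, precision = a$precision, recall = a$recall)
    }
  }
  tab <- do.call(rbind, rows)
  for (k in tissues) {
    sub <- tab[tab$tissue == k & !tab$image %in% c("mean", "sd"), ]
    tab <- rbind(tab,
      data.frame(image = "mean", tissue = k, dsc = mean(sub$dsc),
                 iou = mean(sub$iou), precision = mean(sub$precision),
                 recall = mean(sub$recall)),
      data.frame(image = "sd", tissue = k, dsc = sd(sub$dsc),
                 iou = sd(sub$iou), precision = sd(sub$precision),
                 recall = sd(sub$recall)))
  }
  rownames(tab) <- NULL
  tab
}
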