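#' Skeletal muscle index (SMI)
#'
#' SMI = L3 muscle cross-sectional area (cm²) / height² (m²).
#'
#' @param muscle_area_l3 muscle area at the L3 level, cm² (> 0).
#' @param height standing height in m (> 0).
#' @return SMI in cm²/m².
#' @export
compute_smi <- function(muscle_area_l3, height) {
  if (any(muscle_area_l3 <= 0) || any(height <= 0))
    stop("area and height must be positive")
  muscle_area_l3 / height^2
}

#' Sex-specific SMI cutoffs for sarcopenia
#'
#' Internationally accepted values: 38.5 cm²/m² for females, 52.4 for males.
#'
#' @param sex `"female"` or `"male"`.
#' @return cutoff in cm²/m².
#' @export
smi_cutoff <- function(sex = c("female", "male")) {
  switch(match.arg(sex), female = 38.5, male = 52.4)
}

#' Classify sarcopenia from SMI
#'
#' A patient is sarcopenic iff SMI is strictly below the cutoff.
#'
#' @param smi SMI value(s), cm²/m².
#' @param cutoff threshold, cm²/m² (default female 38.5).
#' @return logical vector, TRUE = sarcopenia.
#' @export
classify_sarcopenia <- function(smi, cutoff = smi_cutoff("female")) {
  if (cutoff <= 0) stop("cutoff must be positive")
  smi < cutoff
}

#' Patient-level screening statistics
#'
#' @param predictions logical vector (TRUE = predicted sarcopenia).
#' @param gold_labels logical vector of reference diagnoses.
#' @param cutoff the cutoff used, recorded in the report.
#' @return object of class `screening_report`: confusion counts, accuracy,
#'   sensitivity, specificity, prevalence.
#' @export
screening_stats <- function(predictions, gold_labels, cutoff = NA_real_) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(gold_labels)) stop("length mismatch")
  p <- as.logical(predictions); g <- as.logical(gold_labels)
  TP <- sum(p & g); FP <- sum(p & !g); FN <- sum(!p & g); TN <- sum(!p & !g)
  structure(list(counts = list(TP = TP, FP = FP, FN = FN, TN = TN),
                 accuracy = (TP + TN) / length(p),
                 sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
                 prevalence = mean(g), cutoff = cutoff,
                 n = length(p)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Sarcopenia screening (n = %d%s)\n", x$n,
              if (is.na(x$cutoff)) "" else sprintf(", cutoff %.4g", x$cutoff)))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$counts$TP, x$counts$FP,
              x$counts$FN, x$counts$TN))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  prevalence %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity, 100 * x$prevalence))
  invisible(x)
}

#' Empirical ROC curve for SMI-based screening
#'
#' Sweeps the cutoff over every distinct observed SMI value plus -Inf/+Inf
#' sentinels. At cutoff c a patient is called positive (sarcopenic) when
#' smi < c, so TPR and FPR are nondecreasing in c and the curve runs from
#' (0, 0) to (1, 1).
#'
#' @param smis numeric SMI values.
#' @param gold_labels logical reference diagnoses (both classes required).
#' @return object of class `roc_curve`: data frame `points` with cutoff,
#'   fpr, tpr.
#' @export
roc_curve <- function(smis, gold_labels) {
  g <- as.logical(gold_labels)
  if (length(smis) != length(g)) stop("length mismatch")
  if (all(g) || !any(g)) stop("both classes must be present")
  cuts <- c(-Inf, sort(unique(smis)), Inf)
  np <- sum(g); nn <- sum(!g)
  tpr <- vapply(cuts, function(c) sum(smis < c & g) / np, 0)
  fpr <- vapply(cuts, function(c) sum(smis < c & !g) / nn, 0)
  structure(list(points = data.frame(cutoff = cuts, fpr = fpr, tpr = tpr)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.4f\n", nrow(x$points), auc(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "1 - specificity (FPR)",
       ylab = "sensitivity (TPR)", main = sprintf("ROC (AUC = %.3f)", auc(x)),
       ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) polyline.
#'
#' @param curve a [roc_curve()] object.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  p <- curve$points
  o <- order(p$fpr, p$tpr)
  f <- p$fpr[o]; t <- p$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = TPR - FPR over the ROC points. Ties are broken in favor of
#' higher TPR (screening prefers sensitivity), then lower cutoff.
#'
#' @param curve a [roc_curve()] object.
#' @return list: cutoff, tpr, fpr, J.
#' @export
youden_optimal <- function(curve) {
  p <- curve$points
  J <- p$tpr - p$fpr
  best <- which(J == max(J))
  if (length(best) > 1) best <- best[p$tpr[best] == max(p$tpr[best])]
  if (length(best) > 1) best <- best[which.min(p$cutoff[best])]
  list(cutoff = p$cutoff[best], tpr = p$tpr[best], fpr = p$fpr[best],
       J = J[best])
}
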