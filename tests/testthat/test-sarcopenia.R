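test_that("SMI arithmetic and classification boundaries", {
  expect_equal(compute_smi(88.2, 1.5), 39.2)
  expect_equal(compute_smi(98.56, 1.6), 38.5)
  expect_equal(compute_smi(77, 1.0), 77)
  expect_error(compute_smi(-1, 1.6), "positive")
  expect_error(compute_smi(80, 0), "positive")
  expect_true(classify_sarcopenia(38.4, 38.5))
  expect_false(classify_sarcopenia(38.5, 38.5))      # strict inequality
  expect_true(classify_sarcopenia(52.0, smi_cutoff("male")))
  expect_equal(smi_cutoff("female"), 38.5)
  expect_equal(smi_cutoff("male"), 52.4)
})

test_that("screening statistics reproduce hand arithmetic", {
  pred <- c(rep(TRUE, 7), rep(FALSE, 1), rep(FALSE, 8), rep(TRUE, 4))
  gold <- c(rep(TRUE, 8), rep(FALSE, 12))
  r <- screening_stats(pred, gold)
  expect_equal(r$counts, list(TP = 7L, FP = 4L, FN = 1L, TN = 8L))
  expect_equal(r$sensitivity, 0.875)
  expect_equal(r$specificity, 8 / 12)
  expect_equal(r$accuracy, 0.75)
  perfect <- screening_stats(gold, gold)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  expect_error(screening_stats(logical(0), logical(0)), "empty")
})

test_that("ROC sweep is monotone with correct endpoints; label reversal reflects it", {
  set.seed(21)
  smi <- c(rnorm(40, 33, 3), rnorm(60, 44, 3))
  lab <- c(rep(TRUE, 40), rep(FALSE, 60))
  roc <- roc_curve(smi, lab)
  p <- roc$points
  expect_true(all(diff(p$fpr) >= 0))
  expect_true(all(diff(p$tpr) >= 0))
  expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
  expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
  # reversed labels swap the roles of TPR and FPR at every cutoff
  roc_rev <- roc_curve(smi, !lab)
  expect_equal(roc_rev$points$tpr, roc$points$fpr)
  expect_equal(roc_rev$points$fpr, roc$points$tpr)
  expect_equal(auc(roc_rev), 1 - auc(roc), tolerance = 1e-12)
  # perfectly separated classes pass through (0, 1)
  sep <- roc_curve(c(30, 31, 32, 50, 51), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(any(sep$points$fpr == 0 & sep$points$tpr == 1))
  expect_equal(auc(sep), 1)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic and matches pROC", {
  set.seed(13)
  for (trial in 1:10) {
    smi <- round(c(rnorm(15, 35, 4), rnorm(20, 42, 4)), 1)  # ties likely
    lab <- c(rep(TRUE, 15), rep(FALSE, 20))
    a <- auc(roc_curve(smi, lab))
    # oracle: P(pos < neg) + 0.5 P(tie) by enumeration
    pos <- smi[lab]; neg <- smi[!lab]
    u <- 0
    for (x in pos) for (y in neg) u <- u + (x < y) + 0.5 * (x == y)
    expect_equal(a, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(14)
  smi <- c(rnorm(30, 35, 5), rnorm(40, 43, 5))
  lab <- c(rep(1, 30), rep(0, 40))
  a <- auc(roc_curve(smi, lab))
  pr <- pROC::roc(lab, smi, direction = ">", quiet = TRUE)
  expect_equal(a, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("null-label ROC sits near the diagonal; noise-free ROC is perfect", {
  coh <- generate_cohort(cohort_spec(n_patients = 2000L), seed = 31)
  # noise-free: labels are a deterministic threshold of SMI
  expect_equal(auc(roc_curve(coh$smi, coh$label)), 1)
  # permutation null
  set.seed(32)
  expect_lt(abs(auc(roc_curve(coh$smi, sample(coh$label))) - 0.5), 0.05)
})

test_that("Youden argmax, tie-breaking, and degenerate curves", {
  curve <- structure(list(points = data.frame(
    cutoff = c(-Inf, 30, 35, 40, Inf),
    fpr = c(0, 0.0, 0.1, 0.3, 1),
    tpr = c(0, 0.0, 0.6, 0.9, 1))), class = "roc_curve")
  y <- youden_optimal(curve)
  expect_equal(y$J, 0.6)                    # J = (0, 0, .5, .6, 0) -> 4th point
  expect_equal(y$cutoff, 40)
  # perfect classifier reaches J = 1
  sep <- roc_curve(c(30, 31, 50, 51), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youden_optimal(sep)$J, 1)
  # diagonal curve: J = 0 everywhere, deterministic tie-break
  diagc <- structure(list(points = data.frame(cutoff = c(-Inf, 1, Inf),
                                              fpr = c(0, 0.5, 1),
                                              tpr = c(0, 0.5, 1))),
                     class = "roc_curve")
  yd <- youden_optimal(diagc)
  expect_equal(yd$J, 0)
  expect_equal(yd$tpr, 1)                   # highest-TPR tie-break
  # sensitivity at the Youden point >= sensitivity at equal specificity
  set.seed(41)
  smi <- c(rnorm(50, 34, 4), rnorm(70, 43, 4))
  lab <- c(rep(TRUE, 50), rep(FALSE, 70))
  roc <- roc_curve(smi, lab)
  yo <- youden_optimal(roc)
  same_spec <- roc$points[roc$points$fpr == yo$fpr, ]
  expect_true(all(yo$tpr >= same_spec$tpr))
})

test_that("Youden optimization recovers a planted cutoff from noisy areas", {
  recovered <- vapply(1:5, function(s) {
    coh <- generate_cohort(cohort_spec(n_patients = 1000L,
                                       prevalence_target = 0.383),
                           planted_cutoff = 38.5, seed = 100 + s)
    set.seed(200 + s)
    noisy <- coh$muscle_area_cm2 + rnorm(1000, 0, 3)
    res <- screen_cohort(coh, measured_areas = noisy)
    res$youden$cutoff
  }, 0)
  expect_true(all(abs(recovered - 38.5) <= 1.5))
})

test_that("screen_cohort ties the pieces together", {
  coh <- generate_cohort(cohort_spec(n_patients = 264L), seed = 77)
  res <- screen_cohort(coh)
  # noise-free screening at the planted cutoff is perfect
  expect_equal(res$report$accuracy, 1)
  expect_equal(res$auc, 1)
  expect_equal(res$report$counts$TP + res$report$counts$FN, sum(coh$label))
})
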