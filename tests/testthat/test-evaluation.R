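test_that("ROC/AUC handles separation, ties and degenerate scores", {
  expect_equal(roc_curve(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_equal(roc_curve(c(0.1, 0.9), c(1, 0))$auc, 0)
  # constant scores: random-guess AUC
  expect_equal(roc_curve(rep(0.4, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), class = "hsim_single_class")
  # 12-point toy with ties equals pair counting
  s <- c(0.1, 0.3, 0.3, 0.5, 0.5, 0.5, 0.7, 0.7, 0.8, 0.9, 0.9, 1.0)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 1)
  expect_equal(roc_curve(s, y)$auc, auc_pair_oracle(s, y))
  r <- roc_curve(s, y)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
})

test_that("AUC properties: monotone invariance, complement, reference agreement", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:120, 1)
    s <- round(runif(n), 2) # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- roc_curve(s, y)$auc
    expect_equal(a, auc_pair_oracle(s, y))
    # strictly monotone transforms leave AUC unchanged
    expect_equal(roc_curve(exp(s), y)$auc, a)
    expect_equal(roc_curve(s^3 + 2 * s, y)$auc, a)
    expect_equal(roc_curve(stats::qlogis(pmin(pmax(s, 0.01), 0.99)), y)$auc, a,
                 tolerance = 1e-12)
    # complement identity
    expect_equal(roc_curve(-s, y)$auc, 1 - a)
  }
  skip_if_not_installed("pROC")
  set.seed(32)
  s <- round(runif(80), 2); y <- rbinom(80, 1, 0.4)
  expect_equal(roc_curve(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("operating points maximize Youden's J on validation data", {
  # perfectly separated: J = 1, threshold inside the gap
  op <- optimal_operating_point(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))
  expect_equal(op$j, 1)
  expect_gt(op$threshold, 0.2)
  expect_lte(op$threshold, 0.8)
  # grid-search oracle over all candidate thresholds
  set.seed(41)
  s <- c(rnorm(60, 0), rnorm(60, 1.6))
  y <- rep(0:1, each = 60)
  op2 <- optimal_operating_point(roc_curve(s, y))
  cand <- c(Inf, sort(unique(s), decreasing = TRUE))
  j_at <- sapply(cand, function(t) {
    mean(s[y == 1] >= t) - mean(s[y == 0] >= t)
  })
  expect_equal(op2$j, max(j_at))
  expect_true(op2$threshold >= 0 && op2$threshold <= 1.6 + 3)
  # symmetric overlap at equal n: threshold lies between the class means
  expect_gt(op2$threshold, 0 - 0.5)
  expect_lt(op2$threshold, 1.6 + 0.5)
  # degenerate single-threshold curve returns that threshold
  op3 <- optimal_operating_point(roc_curve(c(0.5, 0.5), c(1, 0)))
  expect_true(op3$threshold %in% c(0.5, Inf))
})

test_that("thresholded metrics match a hand-tabulated confusion", {
  pred <- matrix(c(0.9, 0.8, 0.2, 0.6, 0.1, 0.3, 0.7, 0.4, 0.95), 3, 3)
  gt <- matrix(c(2L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L), 3, 3)
  mask <- matrix(TRUE, 3, 3)
  m <- metrics_at_threshold(pred, gt, mask, 0.5)
  # by hand: scores >= 0.5 -> pred pos {0.9,0.8,0.6,0.7,0.95}; labels tumor at
  # positions with gt 2: (1,1)=0.9 TP, (2,1)=0.8 TP, (1,2)=0.6 TP, (1,3)=0.7 TP,
  # (3,3)=0.95 TP; fp: none of 0.5+ on gt 1; negatives: 0.2 gt1 TN, 0.1 gt1 TN,
  # 0.3 gt1 TN, 0.4 gt1 TN
  expect_equal(unname(m$counts), c(5L, 0L, 4L, 0L))
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # perfect and inverted predictors
  perfect <- matrix(as.numeric(gt == 2L), 3, 3)
  mp <- metrics_at_threshold(perfect, gt, mask, 0.5)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity), c(1, 1, 1))
  mi <- metrics_at_threshold(1 - perfect, gt, mask, 0.5)
  expect_equal(mi$sensitivity + mi$specificity, 0)
  # empty mask flags and returns NAs
  expect_warning(me <- metrics_at_threshold(pred, gt, matrix(FALSE, 3, 3), 0.5),
                 class = "hsim_empty_mask")
  expect_true(is.na(me$accuracy))
})

test_that("paired one-tailed t-test matches the closed form and flips correctly", {
  # diffs 1,2,3: t = 2*sqrt(3), df = 2
  r <- paired_one_tailed_ttest(c(2, 4, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(r$t_statistic, 2 * sqrt(3))
  expect_equal(r$df, 2)
  expect_equal(r$p_one_tailed, stats::pt(2 * sqrt(3), 2, lower.tail = FALSE))
  expect_equal(r$p_one_tailed, 0.037, tolerance = 1e-2)
  # agreement with the reference implementation
  set.seed(51)
  a <- rnorm(12); b <- rnorm(12, 0.3)
  ours <- paired_one_tailed_ttest(a, b, "greater")
  ref <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(ours$t_statistic, unname(ref$statistic))
  expect_equal(ours$p_one_tailed, ref$p.value)
  # antisymmetry: swapping the arguments flips t and maps p to 1 - p
  swap <- paired_one_tailed_ttest(b, a, "greater")
  expect_equal(swap$t_statistic, -ours$t_statistic)
  expect_equal(swap$p_one_tailed, 1 - ours$p_one_tailed)
  # identical samples: t = 0, p = 0.5, flagged
  same <- paired_one_tailed_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_one_tailed, 0.5)
  expect_true(same$flagged)
  # constant nonzero differences: degenerate p, flagged
  const <- paired_one_tailed_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$flagged)
  expect_equal(const$p_one_tailed, 0)
  expect_error(paired_one_tailed_ttest(1, 2), class = "hsim_insufficient_data")
})

test_that("specimen confusion decomposes TN components per the counting rules", {
  # worked rules: true TN predicted T -> TP + FP; true T predicted TN -> TP + FN
  r1 <- specimen_confusion("TN", "T")
  expect_equal(unname(r1$counts), c(1L, 1L, 0L, 0L))
  r2 <- specimen_confusion("T", "TN")
  expect_equal(unname(r2$counts), c(1L, 0L, 0L, 1L))
  # all-correct predictions are perfect
  r3 <- specimen_confusion(c("T", "N", "TN"), c("T", "N", "TN"))
  expect_equal(unname(r3$counts), c(2L, 0L, 2L, 0L))
  expect_equal(r3$accuracy, 1)
  expect_equal(c(r3$sensitivity, r3$specificity, r3$ppv, r3$npv), rep(1, 4))
  # 10-specimen table counted by hand:
  # T->T (TP), T->N (FN), T->TN (TP+FN), N->N (TN), N->T (FP), N->TN (TN+FP),
  # TN->TN (TP+TN), TN->T (TP+FP), TN->N (TN+FN), TN->TN (TP+TN)
  truth <- c("T", "T", "T", "N", "N", "N", "TN", "TN", "TN", "TN")
  pred <- c("T", "N", "TN", "N", "T", "TN", "TN", "T", "N", "TN")
  r <- specimen_confusion(truth, pred)
  expect_equal(unname(r$counts["tp"]), 2L + 2L + 1L) # T->T, T->TN, TN->TN x2, TN->T
  expect_equal(unname(r$counts["fp"]), 1L + 1L + 1L) # N->T, N->TN, TN->T
  expect_equal(unname(r$counts["tn"]), 1L + 1L + 2L + 1L) # N->N, N->TN, TN->TN x2, TN->N
  expect_equal(unname(r$counts["fn"]), 1L + 1L + 1L) # T->N, T->TN, TN->N
  expect_equal(r$accuracy, (5 + 5) / 16)
  expect_error(specimen_confusion("T", "X"), class = "hsim_format_error")
})

test_that("distance reports aggregate per-patient rows faithfully", {
  spec <- tiny_spec()
  coh <- generate_cohort(3, spec, seed = 6)
  maps <- lapply(coh$scenes[grep("_TN$", names(coh$scenes))], function(sc) {
    cal <- calibrate(sc$raw, sc$frames)
    # proxy score: normalized band-0 reflectance (monotone in class mix)
    v <- cal$values[, , 1]
    v[!sc$tissue_mask] <- NA
    1 - (v - min(v, na.rm = TRUE)) / diff(range(v, na.rm = TRUE))
  })
  rep <- distance_report(maps, coh, d_grid = c(0, 0.5, 1), threshold = 0.5,
                         trim_px = 2)
  expect_equal(nrow(rep), 9L)
  # n_pixels nonincreasing in d within each patient
  for (pid in unique(rep$patient_id)) {
    sub <- rep[rep$patient_id == pid, ]
    expect_true(all(diff(sub[order(sub$d_mm), "n_pixels"]) <= 0))
  }
  # aggregate equals brute-force recomputation from the rows
  agg <- aggregate_report(rep, "auc")
  for (d in c(0, 0.5, 1)) {
    v <- rep$auc[rep$d_mm == d & rep$attainable & !is.na(rep$auc)]
    expect_equal(agg$mean[agg$d_mm == d], mean(v))
    expect_equal(agg$median[agg$d_mm == d], stats::median(v))
    expect_equal(agg$n_patients[agg$d_mm == d], length(v))
  }
  # modality comparison plumbing: a modality against itself is a flagged tie
  cmp <- compare_modalities(rep, rep, d_mm = 0)
  expect_true(cmp$flagged)
  expect_equal(cmp$p_one_tailed, 0.5)
})
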