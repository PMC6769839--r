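#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= threshold`), with tied scores crossing the threshold
#' simultaneously; the trapezoidal area under the resulting curve equals the
#' Mann-Whitney pair-counting statistic (concordant pairs plus half the
#' ties, over `n1 * n0`). Constant scores give AUC 0.5 (random guess).
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   cancer-like).
#' @param labels 0/1 or logical labels (1 = positive class); both classes
#'   must be present.
#' @return an object of class `roc_curve`: `thresholds`, `fpr`, `tpr`
#'   (nondecreasing, starting at 0,0 and ending at 1,1) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    hsim_stop("AUC undefined: labels contain a single class", "hsim_single_class")
  }
  u <- sort(unique(scores), decreasing = TRUE)
  pos_at <- vapply(split(labels, match(scores, u)), function(l) sum(l == 1L), integer(1))
  cnt_at <- vapply(split(labels, match(scores, u)), length, integer(1))
  ord <- order(as.integer(names(pos_at)))
  pos_at <- pos_at[ord]; cnt_at <- cnt_at[ord]
  tpr <- unname(c(0, cumsum(pos_at) / n1))
  fpr <- unname(c(0, cumsum(cnt_at - pos_at) / n0))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, u), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Validation-derived operating point
#'
#' Selects the score threshold maximizing Youden's J = TPR - FPR on a
#' validation ROC curve; ties are broken toward higher specificity (lower
#' FPR), then toward the higher threshold. The chosen threshold is applied
#' unchanged to test data, so test labels are never consulted.
#'
#' @param roc a [roc_curve()] computed on validation data.
#' @param source optional identifier of the validation set, recorded on the
#'   result.
#' @return list with `threshold`, `j`, `sensitivity`, `specificity`,
#'   `source`.
#' @export
optimal_operating_point <- function(roc, source = NULL) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[order(roc$fpr[best], -roc$thresholds[best])][1]
  list(threshold = roc$thresholds[best], j = j[best],
       sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best],
       source = source)
}

# confusion counts and derived metrics for score >= threshold
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  n <- tp + fp + tn + fn
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       accuracy = if (n) (tp + tn) / n else NA_real_,
       sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn) tn / (tn + fn) else NA_real_)
}

#' Pixel metrics at a fixed threshold
#'
#' Confusion counts over the included pixels of an evaluation mask, with the
#' standard definitions: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' plus PPV = TP/(TP+FP) and NPV = TN/(TN+FN). (A common prose formulation describes
#' sensitivity as a ratio over "total positive predictions", which is the
#' definition of precision/PPV; both quantities are reported here so either
#' reading is available.)
#'
#' @param predmap numeric H x W probability map.
#' @param gt_mask integer H x W label mask (1 normal, 2 tumor).
#' @param eval_mask an [exclusion_mask()] result (or logical H x W matrix).
#' @param threshold score cut selected on validation data.
#' @return list with `counts`, `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
metrics_at_threshold <- function(predmap, gt_mask, eval_mask, threshold) {
  included <- if (inherits(eval_mask, "evaluation_mask")) eval_mask$included else eval_mask
  stopifnot(is.matrix(predmap), identical(dim(predmap), dim(gt_mask)),
            identical(dim(predmap), dim(included)))
  if (!any(included)) {
    hsim_warn("evaluation mask is empty; metrics undefined", "hsim_empty_mask")
    return(list(counts = c(tp = 0L, fp = 0L, tn = 0L, fn = 0L), accuracy = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_, ppv = NA_real_,
                npv = NA_real_))
  }
  classification_metrics(predmap[included], as.integer(gt_mask[included] == 2L), threshold)
}

#' Distance-stratified performance report
#'
#' Computes AUC and thresholded metrics per patient and per margin distance.
#' For every patient, the pixels of that patient's scenes in `predmaps` are
#' pooled; at each distance `d` the evaluation mask removes pixels within
#' `d` mm of the tumor-normal interface (default exclusion reading). Scenes
#' without an interface (pure T or N specimens) have no margin, so their
#' pixels are retained at every `d`. Patients for whom a distance leaves no
#' pixels of both classes are marked unattainable at that `d` and are
#' dropped from aggregates.
#'
#' @param predmaps named list (by scene id) of probability maps
#'   ([reconstruct_heatmap()] results or bare matrices).
#' @param cohort the cohort holding the corresponding scenes.
#' @param d_grid margin distances in mm (default 0-3 mm in 0.5 mm steps).
#' @param threshold scalar score cut, or named vector keyed by scene id
#'   (e.g. per-fold validation thresholds).
#' @param trim_px edge-trim radius in pixels.
#' @param mode distance semantics passed to [exclusion_mask()].
#' @return a `data.frame` with one row per (patient, d): `patient_id`,
#'   `modality`, `d_mm`, `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `n_pixels`, `attainable`.
#' @export
distance_report <- function(predmaps, cohort, d_grid = seq(0, 3, by = 0.5),
                            threshold = 0.5, trim_px = 3, mode = "exclude") {
  ids <- names(predmaps)
  stopifnot(length(ids) > 0, all(ids %in% names(cohort$scenes)))
  per_scene <- lapply(ids, function(id) {
    sc <- cohort$scenes[[id]]
    pm <- predmaps[[id]]
    values <- if (inherits(pm, "heat_map")) pm$values else pm
    if (!identical(dim(values), dim(sc$gt_mask))) {
      hsim_stop(sprintf("prediction map for %s does not match the scene shape", id),
                "hsim_format_error")
    }
    trimmed <- trim_tissue_edge(sc$tissue_mask, trim_px)
    both <- any(sc$gt_mask == 1L) && any(sc$gt_mask == 2L)
    dm <- if (both) distance_to_margin(sc$gt_mask, sc$raw$resolution_um_per_px) else NULL
    thr <- if (length(threshold) == 1L && is.null(names(threshold))) threshold else threshold[[id]]
    list(id = id, patient = sc$meta$patient_id, modality = sc$meta$modality,
         values = values, gt = sc$gt_mask, trimmed = trimmed, distmap = dm,
         threshold = thr)
  })
  names(per_scene) <- ids
  patients <- unique(vapply(per_scene, `[[`, character(1), "patient"))
  rows <- list()
  for (pid in patients) {
    group <- Filter(function(s) s$patient == pid, per_scene)
    for (d in d_grid) {
      scores <- c(); labels <- c(); preds <- c()
      for (s in group) {
        inc <- if (is.null(s$distmap)) {
          s$trimmed
        } else {
          sel <- if (mode == "exclude") s$distmap$values_mm >= d else s$distmap$values_mm <= d
          s$trimmed & !is.na(s$distmap$values_mm) & sel
        }
        if (!any(inc)) next
        scores <- c(scores, s$values[inc])
        labels <- c(labels, as.integer(s$gt[inc] == 2L))
        preds <- c(preds, as.integer(s$values[inc] >= s$threshold))
      }
      keep <- !is.na(scores)
      scores <- scores[keep]; labels <- labels[keep]; preds <- preds[keep]
      attainable <- length(scores) > 0 && length(unique(labels)) == 2L
      auc <- if (attainable) roc_curve(scores, labels)$auc else NA_real_
      tp <- sum(preds == 1L & labels == 1L); fp <- sum(preds == 1L & labels == 0L)
      tn <- sum(preds == 0L & labels == 0L); fn <- sum(preds == 0L & labels == 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, modality = group[[1]]$modality, d_mm = d, auc = auc,
        accuracy = if (length(labels)) (tp + tn) / length(labels) else NA_real_,
        sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
        ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
        npv = if (tn + fn) tn / (tn + fn) else NA_real_,
        n_pixels = length(labels), attainable = attainable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a distance report across patients
#'
#' Median and mean (with standard error) of a metric at each margin
#' distance, over the patients for whom that distance is attainable; the
#' shrinking per-distance sample size is reported alongside.
#'
#' @param report a [distance_report()] data.frame.
#' @param metric column to aggregate (default `"auc"`).
#' @return data.frame with `d_mm`, `n_patients`, `median`, `mean`, `sem`.
#' @export
aggregate_report <- function(report, metric = "auc") {
  stopifnot(metric %in% names(report))
  out <- lapply(split(report, report$d_mm), function(df) {
    v <- df[[metric]][df$attainable & !is.na(df[[metric]])]
    data.frame(d_mm = df$d_mm[1], n_patients = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$d_mm), ]
}

#' Paired one-tailed t-test
#'
#' Closed-form paired t-test, `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1`, used for per-patient modality comparisons. One-tailed:
#' `alternative = "greater"` tests whether `a` exceeds `b`. Zero-variance
#' differences are flagged rather than raised as errors: all-zero
#' differences give `t = 0, p = 0.5`; constant nonzero differences give an
#' infinite t and a degenerate p of 0 or 1.
#'
#' @param a,b paired numeric vectors (e.g. per-patient AUCs of two imaging
#'   modalities); pairs with an `NA` on either side are dropped.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return an object of class `paired_ttest`: `t_statistic`, `df`,
#'   `p_one_tailed`, `direction`, `mean_difference`, `n`, `flagged`.
#' @export
paired_one_tailed_ttest <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2L) hsim_stop("need at least 2 complete pairs", "hsim_insufficient_data")
  sd_d <- stats::sd(d)
  flagged <- sd_d == 0
  t_stat <- if (!flagged) {
    mean(d) / (sd_d / sqrt(n))
  } else if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  p <- if (alternative == "greater") {
    stats::pt(t_stat, n - 1, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, n - 1, lower.tail = TRUE)
  }
  structure(list(t_statistic = t_stat, df = n - 1, p_one_tailed = p,
                 direction = alternative, mean_difference = mean(d), n = n,
                 flagged = flagged),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("<paired_ttest> t = %.4g (df = %d), one-tailed p (%s) = %.4g%s\n",
              x$t_statistic, x$df, x$direction, x$p_one_tailed,
              if (x$flagged) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Compare two modalities' distance reports
#'
#' Pairs patients present (and attainable) in both reports at a given margin
#' distance and runs the one-tailed paired t-test on the chosen metric.
#'
#' @param report_a,report_b [distance_report()] data.frames for the two
#'   modalities.
#' @param d_mm margin distance at which to compare.
#' @param metric metric column (default `"auc"`).
#' @param alternative `"greater"` tests modality a > modality b.
#' @return a `paired_ttest` object.
#' @export
compare_modalities <- function(report_a, report_b, d_mm = 0, metric = "auc",
                               alternative = "greater") {
  pick <- function(r) {
    r <- r[r$d_mm == d_mm & r$attainable & !is.na(r[[metric]]), ]
    stats::setNames(r[[metric]], r$patient_id)
  }
  a <- pick(report_a); b <- pick(report_b)
  common <- intersect(names(a), names(b))
  paired_one_tailed_ttest(a[common], b[common], alternative = alternative)
}

#' Specimen-type confusion metrics
#'
#' Scores specimen-type calls (T, TN, N) against ground truth by
#' decomposing tumor-involved margins into tumor and normal components on
#' both sides: matched components count as true positives (tumor) or true
#' negatives (normal); a true TN predicted as all-T adds a true positive and
#' a false positive, while a true T predicted as TN adds a true positive
#' and a false negative.
#'
#' @param true_types,predicted_types character vectors with entries in
#'   `c("T", "TN", "N")`.
#' @return an object of class `specimen_confusion`: `counts` (tp/fp/tn/fn),
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
specimen_confusion <- function(true_types, predicted_types) {
  stopifnot(length(true_types) == length(predicted_types))
  ok <- c("T", "TN", "N")
  if (!all(true_types %in% ok) || !all(predicted_types %in% ok)) {
    hsim_stop("specimen types must be T, TN or N", "hsim_format_error")
  }
  comp <- function(x) switch(x, T = "T", N = "N", TN = c("T", "N"))
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(true_types)) {
    st <- comp(true_types[i]); sp <- comp(predicted_types[i])
    for (c_true in st) {
      if (c_true %in% sp) {
        if (c_true == "T") tp <- tp + 1L else tn <- tn + 1L
      } else {
        if (c_true == "T") fn <- fn + 1L else fp <- fp + 1L
      }
    }
    if (all(st %in% sp)) {
      for (c_extra in setdiff(sp, st)) {
        if (c_extra == "T") fp <- fp + 1L else fn <- fn + 1L
      }
    }
  }
  n <- tp + fp + tn + fn
  structure(list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 accuracy = (tp + tn) / n,
                 sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
                 ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn) tn / (tn + fn) else NA_real_),
            class = "specimen_confusion")
}

#' @export
print.specimen_confusion <- function(x, ...) {
  cat(sprintf("<specimen_confusion> TP %d, FP %d, TN %d, FN %d | acc %.2f sens %.2f spec %.2f\n",
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"],
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
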