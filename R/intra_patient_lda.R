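#' Extract per-pixel spectral features
#'
#' One row per included pixel of a calibrated scene; labels come from the
#' registered ground truth (1 = SCC). Row provenance (scene id and pixel
#' coordinates) is kept so downstream leakage audits can trace every feature
#' row to its source pixel.
#'
#' @param scene a [specimen_scene()].
#' @param mask logical H x W matrix of pixels to extract (typically the
#'   edge-trimmed tissue mask).
#' @param calibrated optional pre-calibrated [hypercube()] for the scene, to
#'   avoid recalibrating.
#' @return list with `spectra` (n x C matrix), `labels` (0/1 integer),
#'   `coords` (n x 2), `scene_id`.
#' @export
extract_pixel_features <- function(scene, mask, calibrated = NULL) {
  stopifnot(inherits(scene, "specimen_scene"), is.matrix(mask))
  if (!any(mask)) hsim_stop("feature extraction mask is empty", "hsim_empty_mask")
  cube <- if (is.null(calibrated)) calibrate(scene$raw, scene$frames) else calibrated
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  idx <- which(mask)
  list(spectra = flat[idx, , drop = FALSE],
       labels = as.integer(scene$gt_mask[idx] == 2L),
       coords = which(mask, arr.ind = TRUE),
       scene_id = scene_id(scene))
}

#' Fit a single shrinkage-LDA learner
#'
#' Two-class linear discriminant with a shrunk pooled covariance
#' `Sigma = (1 - gamma) S + gamma diag(S)`. The discriminant direction is
#' `w = Sigma^{-1} (mu1 - mu0)` and posteriors follow the two-class Gaussian
#' formula with empirical class priors, i.e. a logistic function of the
#' linear score.
#'
#' @param x n x C feature matrix.
#' @param y 0/1 labels (1 = SCC); both classes must be present.
#' @param shrinkage gamma in \[0, 1\]; with `gamma = 0` the sample size must
#'   exceed the feature dimension or the pooled covariance is singular.
#' @return an object of class `hsim_lda` with fields `w`, `bias`, `means`,
#'   `priors`.
#' @export
fit_lda <- function(x, y, shrinkage = 0.1) {
  stopifnot(is.matrix(x), length(y) == nrow(x), shrinkage >= 0, shrinkage <= 1)
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) hsim_stop("both classes must be present to fit LDA", "hsim_fit_error")
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  c0 <- stats::cov(x[y == 0L, , drop = FALSE])
  c1 <- stats::cov(x[y == 1L, , drop = FALSE])
  S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  Sigma <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(x))
  w <- tryCatch(solve(Sigma, mu1 - mu0), error = function(e) {
    hsim_stop("pooled covariance is singular; increase `shrinkage`", "hsim_fit_error")
  })
  bias <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  structure(list(w = w, bias = bias, means = rbind(normal = mu0, scc = mu1),
                 priors = c(normal = n0, scc = n1) / (n0 + n1)),
            class = "hsim_lda")
}

#' @export
predict.hsim_lda <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  as.vector(sigmoid(newdata %*% object$w + object$bias))
}

#' Ensemble-LDA configuration
#'
#' @param n_learners total learner count (default 500).
#' @param n_folds cross-validation folds (default 5); learners are split
#'   evenly across folds and each fold's learners are bagged from the other
#'   folds' rows.
#' @param bag_fraction fraction of training rows drawn (with replacement) per
#'   learner; `1` uses all training rows without resampling.
#' @param shrinkage covariance regularization passed to [fit_lda()].
#' @param seed RNG seed for fold assignment and bagging.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_learners = 500, n_folds = 5, bag_fraction = 0.632,
                            shrinkage = 0.1, seed = 1) {
  stopifnot(n_learners >= 1, n_folds >= 2, bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_learners = as.integer(n_learners), n_folds = as.integer(n_folds),
                 bag_fraction = bag_fraction, shrinkage = shrinkage, seed = seed),
            class = "ensemble_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a personalized intra-patient ensemble
#'
#' The personalized protocol: an ensemble of shrinkage-LDA learners trained
#' and validated on one patient's own primary-tumor (T) and all-normal (N)
#' specimens; the patient's tumor-involved margin (TN) specimen is reserved
#' for testing via [predict_map()]. Pixel rows are split into stratified
#' folds; the learner budget is divided across folds and each fold's
#' learners are fit on bootstrap bags of the remaining folds' rows. Held-out
#' validation scores (mean posterior of the fold's learners on the fold's
#' own rows) are recorded for operating-point selection.
#'
#' @param t_scene,n_scene the patient's T and N [specimen_scene()]s.
#' @param config an [ensemble_config()].
#' @param trim_px edge-trim radius (pixels) applied to the tissue masks.
#' @return an object of class `intra_patient_ensemble`: fields `learners`
#'   (list of `hsim_lda`), `learner_fold`, `val_scores`, `val_labels`,
#'   `val_fold`, `config`, `grid`, `patient_id`, `train_row_fold`.
#' @export
train_intra_patient <- function(t_scene, n_scene, config = ensemble_config(),
                                trim_px = 3) {
  stopifnot(inherits(t_scene, "specimen_scene"), inherits(n_scene, "specimen_scene"),
            inherits(config, "ensemble_config"))
  if (!identical(t_scene$meta$patient_id, n_scene$meta$patient_id)) {
    hsim_stop("T and N scenes must come from the same patient", "hsim_protocol_error")
  }
  feats <- lapply(list(t_scene, n_scene), function(sc) {
    extract_pixel_features(sc, trim_tissue_edge(sc$tissue_mask, trim_px))
  })
  x <- rbind(feats[[1]]$spectra, feats[[2]]$spectra)
  y <- c(feats[[1]]$labels, feats[[2]]$labels)
  if (!any(y == 1L) || !any(y == 0L)) {
    hsim_stop("patient's T and N specimens do not provide both classes", "hsim_fit_error")
  }
  k <- config$n_folds
  with_seed(config$seed, {
    fold <- stratified_folds(y, k)
    counts <- table(factor(fold, levels = seq_len(k)), factor(y, levels = 0:1))
    if (any(counts < 2)) {
      hsim_stop(paste0("insufficient pixels per fold/class: ",
                       paste(utils::capture.output(print(counts)), collapse = " ")),
                "hsim_fit_error")
    }
    per_fold <- rep(config$n_learners %/% k, k)
    per_fold[seq_len(config$n_learners %% k)] <- per_fold[seq_len(config$n_learners %% k)] + 1L
    learners <- list(); learner_fold <- integer(0)
    val_scores <- numeric(length(y)); val_fold <- fold
    for (f in seq_len(k)) {
      train_idx <- which(fold != f)
      fold_learners <- vector("list", per_fold[f])
      for (j in seq_len(per_fold[f])) {
        bag <- if (config$bag_fraction == 1) train_idx else {
          sample(train_idx, round(config$bag_fraction * length(train_idx)), replace = TRUE)
        }
        fold_learners[[j]] <- fit_lda(x[bag, , drop = FALSE], y[bag], config$shrinkage)
      }
      val_idx <- which(fold == f)
      if (length(fold_learners)) {
        scores <- vapply(fold_learners, function(l) predict(l, x[val_idx, , drop = FALSE]),
                         numeric(length(val_idx)))
        val_scores[val_idx] <- if (length(val_idx) == 1L) mean(scores) else rowMeans(as.matrix(scores))
      } else {
        val_scores[val_idx] <- NA_real_ # fewer learners than folds
      }
      learners <- c(learners, fold_learners)
      learner_fold <- c(learner_fold, rep(f, per_fold[f]))
    }
    structure(list(learners = learners, learner_fold = learner_fold,
                   val_scores = val_scores, val_labels = y, val_fold = val_fold,
                   config = config, grid = t_scene$raw$grid,
                   patient_id = t_scene$meta$patient_id,
                   train_row_fold = fold),
              class = "intra_patient_ensemble")
  })
}

#' @export
print.intra_patient_ensemble <- function(x, ...) {
  cat(sprintf("<intra_patient_ensemble> patient %s, %d learners in %d folds, C = %d\n",
              x$patient_id, length(x$learners), x$config$n_folds, x$grid$n_bands))
  invisible(x)
}

#' Per-pixel cancer-probability map from an ensemble
#'
#' Mean posterior over all learners for every tissue pixel of a calibrated
#' scene; background pixels are `NA`.
#'
#' @param ensemble an [train_intra_patient()] result (or any object with a
#'   `learners` list and `grid`).
#' @param scene the test [specimen_scene()] (typically the patient's TN).
#' @return numeric H x W matrix of probabilities in \[0, 1\], `NA` outside
#'   tissue.
#' @export
predict_map <- function(ensemble, scene) {
  stopifnot(inherits(ensemble, "intra_patient_ensemble"),
            inherits(scene, "specimen_scene"))
  if (!identical(ensemble$grid$bands, scene$raw$grid$bands)) {
    hsim_stop("scene wavelength grid does not match the ensemble's", "hsim_grid_error")
  }
  cube <- calibrate(scene$raw, scene$frames)
  feats <- extract_pixel_features(scene, scene$tissue_mask, calibrated = cube)
  acc <- numeric(nrow(feats$spectra))
  for (l in ensemble$learners) acc <- acc + predict(l, feats$spectra)
  out <- matrix(NA_real_, nrow(scene$gt_mask), ncol(scene$gt_mask))
  out[scene$tissue_mask] <- acc / length(ensemble$learners)
  out
}
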