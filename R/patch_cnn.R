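#' Sliding-window patch specification
#'
#' The inter-patient protocol classifies 25 x 25 x C patches cut by a
#' sliding window with a 13-pixel overlap, i.e. a stride of 12 pixels.
#'
#' @param size_px window side length (default 25).
#' @param overlap_px overlap between adjacent windows (default 13); the
#'   stride is `size_px - overlap_px`.
#' @return an object of class `patch_spec` with derived `stride_px`.
#' @export
patch_spec <- function(size_px = 25, overlap_px = 13) {
  stopifnot(overlap_px >= 0, overlap_px < size_px)
  structure(list(size_px = as.integer(size_px), overlap_px = as.integer(overlap_px),
                 stride_px = as.integer(size_px - overlap_px)),
            class = "patch_spec")
}

# 0-based lattice offsets along one axis, plus a final flush window at the
# far edge so border tissue is always covered
patch_offsets <- function(extent, size, stride, flush = TRUE) {
  offs <- seq(0L, extent - size, by = stride)
  if (flush && offs[length(offs)] != extent - size) offs <- c(offs, extent - size)
  offs
}

#' Extract sliding-window patches from a scene
#'
#' Cuts the calibrated cube into `size x size x C` patches on the stride
#' lattice (with a flush row/column at each image edge). In `"training"`
#' mode only patches that are mostly tissue are kept, labeled cancer when
#' the tumor fraction of their tissue pixels is at least 0.5; patches of
#' intermediate purity can be dropped so near-boundary windows do not
#' dilute the training classes. In `"inference"` mode every patch that
#' intersects tissue is kept.
#'
#' @param scene a [specimen_scene()], or a calibrated [hypercube()] if
#'   `gt_mask` is supplied.
#' @param spec a [patch_spec()].
#' @param mode `"inference"` (default) or `"training"`.
#' @param gt_mask label mask, required when `scene` is a bare cube.
#' @param min_tissue minimum tissue fraction for a training patch.
#' @param purity_band training patches with tumor purity strictly inside
#'   this open interval are dropped; `NULL` keeps all.
#' @param calibrated optional pre-calibrated cube.
#' @return list with `patches` (m x size x size x C), `coords` (m x 2,
#'   1-based top-left), `labels`, `purity`, `tissue_frac`, `scene_id`.
#' @export
extract_patches <- function(scene, spec = patch_spec(),
                            mode = c("inference", "training"),
                            gt_mask = NULL, min_tissue = 0.5,
                            purity_band = c(0.2, 0.8), calibrated = NULL) {
  mode <- match.arg(mode)
  if (inherits(scene, "specimen_scene")) {
    cube <- if (is.null(calibrated)) calibrate(scene$raw, scene$frames) else calibrated
    gt_mask <- scene$gt_mask
    sid <- scene_id(scene)
  } else {
    cube <- scene
    if (is.null(gt_mask)) hsim_stop("gt_mask required with a bare cube", "hsim_format_error")
    sid <- NA_character_
  }
  vals <- cube$values
  d <- dim(vals)
  sz <- spec$size_px
  if (d[1] < sz || d[2] < sz) {
    hsim_stop(sprintf("image %dx%d smaller than patch size %d", d[1], d[2], sz),
              "hsim_format_error")
  }
  offs_r <- patch_offsets(d[1], sz, spec$stride_px)
  offs_c <- patch_offsets(d[2], sz, spec$stride_px)
  coords <- as.matrix(expand.grid(row = offs_r + 1L, col = offs_c + 1L))
  tissue <- gt_mask > 0L
  m <- nrow(coords)
  tissue_frac <- purity <- numeric(m)
  for (i in seq_len(m)) {
    rr <- coords[i, 1]:(coords[i, 1] + sz - 1L)
    cc <- coords[i, 2]:(coords[i, 2] + sz - 1L)
    tt <- tissue[rr, cc]
    tissue_frac[i] <- mean(tt)
    purity[i] <- if (any(tt)) mean(gt_mask[rr, cc][tt] == 2L) else NA_real_
  }
  keep <- if (mode == "training") {
    k <- tissue_frac >= min_tissue & !is.na(purity)
    if (!is.null(purity_band)) {
      k <- k & !(purity > purity_band[1] & purity < purity_band[2])
    }
    k
  } else {
    tissue_frac > 0
  }
  coords <- coords[keep, , drop = FALSE]
  purity <- purity[keep]
  tissue_frac <- tissue_frac[keep]
  m <- nrow(coords)
  patches <- array(0, c(m, sz, sz, d[3]))
  for (i in seq_len(m)) {
    patches[i, , , ] <- vals[coords[i, 1]:(coords[i, 1] + sz - 1L),
                             coords[i, 2]:(coords[i, 2] + sz - 1L), ]
  }
  list(patches = patches, coords = coords,
       labels = as.integer(!is.na(purity) & purity >= 0.5),
       purity = purity, tissue_frac = tissue_frac, scene_id = sid)
}

#' Patient-level fold assignment
#'
#' Randomly partitions patients into `k` folds of sizes differing by at most
#' one. All scenes of a patient share one fold, so every fold is a
#' fully-independent test group.
#'
#' @param patients character vector of patient ids.
#' @param k fold count (default 5).
#' @param seed RNG seed; same seed, same assignment.
#' @return named integer vector mapping patient id to fold in `1..k`.
#' @export
assign_folds <- function(patients, k = 5, seed = 1) {
  patients <- unique(patients)
  if (length(patients) < k) {
    hsim_stop(sprintf("%d patients cannot fill %d folds", length(patients), k),
              "hsim_protocol_error")
  }
  with_seed(seed, {
    shuffled <- sample(patients)
    fold <- rep_len(seq_len(k), length(shuffled))
    stats::setNames(fold[order(match(patients, shuffled))], patients)
  })
}

#' Overlap-averaged heat-map reconstruction
#'
#' Each pixel's cancer probability is the exact mean of the scores of all
#' patches covering it; the per-pixel contributing-patch count is returned
#' as `coverage` and pixels no patch covers are `NA`.
#'
#' @param patch_scores numeric vector of per-patch probabilities in \[0, 1\].
#' @param coords m x 2 matrix of 1-based top-left patch coordinates.
#' @param image_shape `c(H, W)`.
#' @param spec the [patch_spec()] the patches were cut with.
#' @return an object of class `heat_map`: list with `values` (H x W, `NA`
#'   where uncovered) and `coverage` (integer H x W).
#' @export
reconstruct_heatmap <- function(patch_scores, coords, image_shape, spec = patch_spec()) {
  stopifnot(length(patch_scores) == nrow(coords), length(image_shape) == 2L)
  sz <- spec$size_px
  if (nrow(coords) > 0 &&
      (min(coords) < 1 || max(coords[, 1]) + sz - 1 > image_shape[1] ||
       max(coords[, 2]) + sz - 1 > image_shape[2])) {
    hsim_stop("patch coordinates fall outside the image", "hsim_format_error")
  }
  acc <- matrix(0, image_shape[1], image_shape[2])
  cnt <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_along(patch_scores)) {
    rr <- coords[i, 1]:(coords[i, 1] + sz - 1L)
    cc <- coords[i, 2]:(coords[i, 2] + sz - 1L)
    acc[rr, cc] <- acc[rr, cc] + patch_scores[i]
    cnt[rr, cc] <- cnt[rr, cc] + 1L
  }
  values <- acc / cnt
  values[cnt == 0L] <- NA_real_
  structure(list(values = values, coverage = cnt), class = "heat_map")
}

#' Run the inter-patient cross-validation experiment
#'
#' The fully-independent protocol: patients are split into `k` patient-level
#' folds; for each fold, a patch CNN is trained on T and N scenes of the
#' other folds' patients (one of those folds held out for validation-based
#' early stopping and operating-point selection) and deployed on the test
#' fold. Experiment `"TvsN"` tests on the held-out patients' T and N scenes;
#' `"TN"` tests on their tumor-involved margin scenes; both can be requested
#' together and share the per-fold models. Every scene receives exactly one
#' test-level heat map.
#'
#' @param cohort a [generate_cohort()] result (or an equivalent list with
#'   `scenes` and `manifest`).
#' @param experiments subset of `c("TvsN", "TN")`.
#' @param spec a [patch_spec()].
#' @param config a [cnn_config()].
#' @param k fold count.
#' @param seed seed for the fold assignment; per-fold model seeds derive
#'   from `config$seed`.
#' @param keep_models keep the fitted `patch_cnn` of each fold (memory)?
#' @return an object of class `inter_patient_result`: `heatmaps` (named by
#'   scene id), `scene_info` data.frame (scene, patient, type, fold,
#'   experiment), `fold_of_patient`, `thresholds` (per-fold validation
#'   operating points), `val_auc` (per fold), `provenance` (per-fold train /
#'   validation / test patient ids and training scene ids), and `models`
#'   when requested.
#' @export
run_inter_patient_experiment <- function(cohort, experiments = c("TvsN", "TN"),
                                         spec = patch_spec(), config = cnn_config(),
                                         k = 5, seed = 1, keep_models = FALSE) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  manifest <- cohort$manifest
  patients <- unique(manifest$patient_id)
  fold_of_patient <- assign_folds(patients, k = k, seed = seed)
  heatmaps <- list()
  info <- list()
  thresholds <- numeric(k)
  val_auc <- numeric(k)
  provenance <- list()
  models <- list()
  calib_cache <- new.env(parent = emptyenv())
  get_cal <- function(sc) {
    id <- scene_id(sc)
    if (is.null(calib_cache[[id]])) calib_cache[[id]] <- calibrate(sc$raw, sc$frames)
    calib_cache[[id]]
  }
  gather_patches <- function(pids) {
    sets <- list()
    for (pid in pids) {
      for (type in c("T", "N")) {
        sc <- cohort$scenes[[paste(pid, type, sep = "_")]]
        if (is.null(sc)) next
        sets[[paste(pid, type)]] <- extract_patches(sc, spec, mode = "training",
                                                    calibrated = get_cal(sc))
      }
    }
    list(patches = do.call(abind1, lapply(sets, `[[`, "patches")),
         labels = unlist(lapply(sets, `[[`, "labels"), use.names = FALSE),
         scene_ids = unlist(lapply(sets, function(s) rep(s$scene_id, length(s$labels))),
                            use.names = FALSE))
  }
  for (f in seq_len(k)) {
    test_pids <- names(fold_of_patient)[fold_of_patient == f]
    other_folds <- setdiff(seq_len(k), f)
    val_fold <- other_folds[1 + (f - 1) %% length(other_folds)]
    val_pids <- names(fold_of_patient)[fold_of_patient == val_fold]
    train_pids <- names(fold_of_patient)[!fold_of_patient %in% c(f, val_fold)]
    train_set <- gather_patches(train_pids)
    val_set <- gather_patches(val_pids)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, f)
    model <- train_fold(train_set, val_set, cfg,
                        wavelengths = cohort$spec$grid$bands)
    val_scores <- predict(model, val_set$patches)
    roc_val <- roc_curve(val_scores, val_set$labels)
    op <- optimal_operating_point(roc_val)
    thresholds[f] <- op$threshold
    val_auc[f] <- roc_val$auc
    provenance[[f]] <- list(fold = f, train_patients = train_pids,
                            val_patients = val_pids, test_patients = test_pids,
                            train_scene_ids = unique(c(train_set$scene_ids,
                                                       val_set$scene_ids)))
    if (keep_models) models[[f]] <- model
    test_types <- unique(unlist(lapply(experiments, function(e) {
      if (e == "TvsN") c("T", "N") else "TN"
    })))
    for (pid in test_pids) {
      for (type in test_types) {
        sc <- cohort$scenes[[paste(pid, type, sep = "_")]]
        if (is.null(sc)) {
          message(sprintf("patient %s lacks a %s scene; skipped", pid, type))
          next
        }
        pp <- extract_patches(sc, spec, mode = "inference", calibrated = get_cal(sc))
        scores <- predict(model, pp$patches)
        hm <- reconstruct_heatmap(scores, pp$coords, dim(sc$gt_mask), spec)
        id <- scene_id(sc)
        heatmaps[[id]] <- hm
        info[[id]] <- data.frame(scene_id = id, patient_id = pid,
                                 specimen_type = type, fold = f,
                                 experiment = if (type == "TN") "TN" else "TvsN",
                                 stringsAsFactors = FALSE)
      }
    }
  }
  scene_info <- do.call(rbind, info)
  rownames(scene_info) <- NULL
  structure(list(heatmaps = heatmaps, scene_info = scene_info,
                 fold_of_patient = fold_of_patient, thresholds = thresholds,
                 val_auc = val_auc, provenance = provenance,
                 models = if (keep_models) models else NULL,
                 experiments = experiments),
            class = "inter_patient_result")
}

#' @export
print.inter_patient_result <- function(x, ...) {
  cat(sprintf("<inter_patient_result> %d folds, %d test heat maps (%s), mean val AUC %.3f\n",
              length(x$thresholds), length(x$heatmaps),
              paste(x$experiments, collapse = "+"), mean(x$val_auc)))
  invisible(x)
}
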