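#' Run the intra-patient study over a cohort
#'
#' For every patient with all three specimen types, trains the personalized
#' ensemble on the patient's T and N scenes, selects the operating point on
#' the pooled held-out validation scores (Youden's J), predicts the
#' patient's TN scene, and assembles the distance-stratified report.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config an [ensemble_config()]; per-patient seeds derive from
#'   `config$seed`.
#' @param trim_px edge-trim radius (pixels).
#' @param d_grid margin distances (mm) for the report.
#' @param mode distance semantics (see [exclusion_mask()]).
#' @return list with `report` ([distance_report()] rows for the TN scenes),
#'   `val_auc` (named per-patient held-out validation AUC), `thresholds`
#'   (named by TN scene id), `predmaps`.
#' @export
run_intra_patient_study <- function(cohort, config = ensemble_config(),
                                    trim_px = 3, d_grid = seq(0, 2, by = 0.5),
                                    mode = "exclude") {
  patients <- unique(cohort$manifest$patient_id)
  predmaps <- list()
  thresholds <- c()
  val_auc <- c()
  for (i in seq_along(patients)) {
    pid <- patients[i]
    t_sc <- cohort$scenes[[paste0(pid, "_T")]]
    n_sc <- cohort$scenes[[paste0(pid, "_N")]]
    tn_sc <- cohort$scenes[[paste0(pid, "_TN")]]
    if (is.null(t_sc) || is.null(n_sc) || is.null(tn_sc)) {
      message(sprintf("patient %s lacks a full T/N/TN triple; skipped", pid))
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    ens <- train_intra_patient(t_sc, n_sc, cfg, trim_px = trim_px)
    roc_val <- roc_curve(ens$val_scores, ens$val_labels)
    op <- optimal_operating_point(roc_val, source = "pooled validation folds")
    id <- scene_id(tn_sc)
    predmaps[[id]] <- predict_map(ens, tn_sc)
    thresholds[id] <- op$threshold
    val_auc[pid] <- roc_val$auc
  }
  if (!length(predmaps)) hsim_stop("no patient had a complete T/N/TN triple", "hsim_protocol_error")
  report <- distance_report(predmaps, cohort, d_grid = d_grid,
                            threshold = thresholds, trim_px = trim_px, mode = mode)
  list(report = report, val_auc = val_auc, thresholds = thresholds,
       predmaps = predmaps)
}

default_pipeline_config <- function() {
  list(out_dir = NULL, seed = 1,
       stages = c("simulate", "intra", "inter", "saliency"),
       cohort = list(n_patients = 10, class_separation = 1, modality = "reflectance",
                     image_size = c(64, 64),
                     grid = list(start_nm = 450, stop_nm = 900, step_nm = 5)),
       lda = list(n_learners = 100, n_folds = 5, bag_fraction = 0.632, shrinkage = 0.1),
       cnn = list(spectral_channels = 16, block_widths = c(8, 8), epochs_max = 12,
                  batch_size = 32, learning_rate = 1e-3, patience = 4),
       patch = list(size_px = 25, overlap_px = 13),
       evaluation = list(d_grid = seq(0, 2, by = 0.5), trim_px = 3, mode = "exclude"),
       saliency = list(classes = "scc"))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Run the end-to-end phantom study
#'
#' Orchestrates simulate -> calibrate -> train -> predict -> evaluate ->
#' saliency from a single configuration (a nested list or the path of a YAML
#' file); any subset of stages can be requested, later stages reusing the
#' in-memory outputs of earlier ones. Identical config and seed give
#' identical reports. When `out_dir` is set, the manifest, reports,
#' aggregates, saliency profiles and a provenance record (config, seeds,
#' versions) are written as CSV/JSON.
#'
#' @param config nested list (see `hsimargin:::default_pipeline_config()`
#'   for the schema and defaults) or path to a YAML file with the same
#'   structure.
#' @return list with `cohort`, `intra` (study list), `inter`
#'   (experiment + reports), `saliency` (profiles), `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  stages <- cfg$stages
  out <- list(config = cfg)
  spec <- scene_spec(image_size = cfg$cohort$image_size,
                     grid = build_band_grid(cfg$cohort$grid$start_nm,
                                            cfg$cohort$grid$stop_nm,
                                            cfg$cohort$grid$step_nm),
                     class_separation = cfg$cohort$class_separation,
                     modality = cfg$cohort$modality)
  if ("simulate" %in% stages) {
    out$cohort <- generate_cohort(cfg$cohort$n_patients, spec,
                                  seed = derive_seed(cfg$seed, 101))
  }
  odir <- cfg$out_dir
  if (!is.null(odir)) {
    dir.create(odir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$cohort)) {
      utils::write.csv(out$cohort$manifest, file.path(odir, "manifest.csv"),
                       row.names = FALSE)
    }
  }
  if ("intra" %in% stages && !is.null(out$cohort)) {
    ec <- ensemble_config(n_learners = cfg$lda$n_learners, n_folds = cfg$lda$n_folds,
                          bag_fraction = cfg$lda$bag_fraction,
                          shrinkage = cfg$lda$shrinkage,
                          seed = derive_seed(cfg$seed, 102))
    out$intra <- run_intra_patient_study(out$cohort, ec,
                                         trim_px = cfg$evaluation$trim_px,
                                         d_grid = cfg$evaluation$d_grid,
                                         mode = cfg$evaluation$mode)
    if (!is.null(odir)) {
      utils::write.csv(out$intra$report, file.path(odir, "intra_report.csv"),
                       row.names = FALSE)
      utils::write.csv(aggregate_report(out$intra$report),
                       file.path(odir, "intra_aggregate_auc.csv"), row.names = FALSE)
    }
  }
  if ("inter" %in% stages && !is.null(out$cohort)) {
    cc <- do.call(cnn_config, c(cfg$cnn, list(seed = derive_seed(cfg$seed, 103))))
    ps <- patch_spec(cfg$patch$size_px, cfg$patch$overlap_px)
    expt <- run_inter_patient_experiment(out$cohort, experiments = c("TvsN", "TN"),
                                         spec = ps, config = cc,
                                         seed = derive_seed(cfg$seed, 104),
                                         keep_models = "saliency" %in% stages)
    thr <- stats::setNames(expt$thresholds[expt$scene_info$fold],
                           expt$scene_info$scene_id)
    split_ids <- split(expt$scene_info$scene_id, expt$scene_info$experiment)
    reports <- lapply(split_ids, function(ids) {
      distance_report(expt$heatmaps[ids], out$cohort,
                      d_grid = cfg$evaluation$d_grid, threshold = thr[ids],
                      trim_px = cfg$evaluation$trim_px, mode = cfg$evaluation$mode)
    })
    out$inter <- list(experiment = expt, reports = reports)
    if (!is.null(odir)) {
      for (nm in names(reports)) {
        utils::write.csv(reports[[nm]],
                         file.path(odir, sprintf("inter_%s_report.csv", tolower(nm))),
                         row.names = FALSE)
        utils::write.csv(aggregate_report(reports[[nm]]),
                         file.path(odir, sprintf("inter_%s_aggregate_auc.csv", tolower(nm))),
                         row.names = FALSE)
      }
    }
  }
  if ("saliency" %in% stages && !is.null(out$inter) &&
      !is.null(out$inter$experiment$models)) {
    model <- out$inter$experiment$models[[1]]
    pids <- out$inter$experiment$provenance[[1]]$test_patients
    ps <- patch_spec(cfg$patch$size_px, cfg$patch$overlap_px)
    sets <- list()
    for (pid in pids) {
      for (type in c("T", "N")) {
        sc <- out$cohort$scenes[[paste(pid, type, sep = "_")]]
        if (!is.null(sc)) sets[[paste(pid, type)]] <- extract_patches(sc, ps, "training")
      }
    }
    patches <- do.call(abind1, lapply(sets, `[[`, "patches"))
    labels <- unlist(lapply(sets, `[[`, "labels"), use.names = FALSE)
    out$saliency <- lapply(stats::setNames(nm = cfg$saliency$classes), function(cl) {
      gradcam_spectral(model, patches, labels, target_class = cl)
    })
    if (!is.null(odir)) {
      for (cl in names(out$saliency)) {
        pr <- out$saliency[[cl]]
        utils::write.csv(data.frame(wavelength_nm = pr$wavelengths,
                                    saliency = pr$saliency),
                         file.path(odir, sprintf("saliency_%s.csv", cl)),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(odir)) {
    prov <- list(config = cfg, package_version = as.character(utils::packageVersion("hsimargin")),
                 r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(odir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
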