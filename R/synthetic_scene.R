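#' Phenomenological spectral model for tissue phantoms
#'
#' Mean-spectrum model with the qualitative features that separate squamous
#' cell carcinoma (SCC) from normal upper-aerodigestive-tract tissue in
#' reflectance imaging: oxygenated-hemoglobin absorption dips at 560 and
#' 565 nm (deeper in SCC, whose metabolic activity is higher), stronger
#' near-infrared attenuation in normal tissue (greater fat, collagen and
#' water content), and a small broad reflectance offset so the classes differ
#' at every band. Shapes are smooth baselines plus Gaussian features, not
#' radiative-transfer simulations. The `"fluorescence"` modality reuses the
#' machinery on an emission-shaped baseline with Gaussian emission peaks
#' instead of absorption dips.
#'
#' @param modality `"reflectance"` (default) or `"fluorescence"`.
#' @param features list of `c(center_nm, width_nm, depth)` Gaussian features;
#'   absorption dips for reflectance, emission peaks for fluorescence.
#' @param normal_feature_scale fraction of the SCC feature depth retained in
#'   the normal-class spectrum (normal mucosa also carries hemoglobin).
#' @param nir_contrast fractional attenuation of the normal-class spectrum at
#'   the long-wavelength end.
#' @param broad_offset fractional broad-band brightening of the SCC spectrum.
#' @param noise_sd additive per-band Gaussian reflectance noise.
#' @param pixel_variation_sd sigma of the per-pixel multiplicative lognormal
#'   brightness field (spatial texture).
#' @return an object of class `spectral_model`.
#' @export
spectral_model <- function(modality = c("reflectance", "fluorescence"),
                           features = list(c(560, 12, 0.18), c(565, 18, 0.14)),
                           normal_feature_scale = 0.35,
                           nir_contrast = 0.25,
                           broad_offset = 0.06,
                           noise_sd = 0.02,
                           pixel_variation_sd = 0.08) {
  modality <- match.arg(modality)
  structure(list(modality = modality, features = features,
                 normal_feature_scale = normal_feature_scale,
                 nir_contrast = nir_contrast, broad_offset = broad_offset,
                 noise_sd = noise_sd, pixel_variation_sd = pixel_variation_sd),
            class = "spectral_model")
}

model_baseline <- function(model, lambda) {
  if (model$modality == "reflectance") {
    0.25 + 0.35 * stats::plogis((lambda - 620) / 80)
  } else {
    0.15 + 0.55 * exp(-(lambda - 570)^2 / (2 * 60^2))
  }
}

model_feature_sum <- function(model, lambda) {
  f <- numeric(length(lambda))
  for (ft in model$features) {
    f <- f + ft[3] * exp(-(lambda - ft[1])^2 / (2 * ft[2]^2))
  }
  f
}

#' Class mean spectrum
#'
#' Evaluates the phantom model's mean spectrum for one tissue class on a
#' wavelength grid. At `separation = 0` the two classes are identical (null
#' model); at the default `separation = 1` every band differs between the
#' classes.
#'
#' @param model a [spectral_model()].
#' @param class `"scc"` or `"normal"`.
#' @param grid a [build_band_grid()] object.
#' @param separation nonnegative scalar scaling every class-difference term.
#' @return numeric vector of length `grid$n_bands`, strictly positive.
#' @export
class_spectrum <- function(model, class = c("scc", "normal"), grid, separation = 1) {
  class <- match.arg(class)
  stopifnot(inherits(model, "spectral_model"), separation >= 0)
  lambda <- grid$bands
  base <- model_baseline(model, lambda)
  feat <- model_feature_sum(model, lambda)
  sign <- if (model$modality == "reflectance") -1 else 1
  nir_start <- if (model$modality == "reflectance") 700 else 650
  nir_width <- if (model$modality == "reflectance") 200 else 70
  s <- if (class == "scc") {
    base * (1 + separation * model$broad_offset) * (1 + sign * separation * feat)
  } else {
    ramp <- pmin(1, pmax(0, (lambda - nir_start) / nir_width))
    base * (1 + sign * separation * model$normal_feature_scale * feat) *
      (1 - separation * model$nir_contrast * ramp)
  }
  pmin(pmax(s, 0.02), 1.5)
}

#' Phantom scene specification
#'
#' Defines the study conditions of the synthetic cohort. Defaults emulate
#' gross-level imaging of excised specimens at phantom scale: 64 x 64 px
#' scenes at 100 um/px (6.4 mm extent, close to typical ~9 x 6 mm excised
#' specimens), the 450-900 nm / 5 nm reflectance grid, ~2% specular-glare
#' pixels, and a 1 mm spectral partial-volume transition at the tumor-normal
#' interface standing in for the ~1 mm registration and margin-depth
#' uncertainty.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param grid wavelength grid for the modality.
#' @param resolution_um_per_px spatial scale of the phantom (um/pixel).
#' @param model a [spectral_model()].
#' @param tumor_geometry list with `center_frac` (blob center of TN scenes as
#'   a fraction of image size), `radius_frac`, and `roughness` (relative
#'   boundary modulation).
#' @param glare_fraction fraction of tissue pixels replaced by flat
#'   near-saturation spectra, in \[0, 0.2\].
#' @param class_separation scalar scaling of the SCC-vs-normal mean
#'   difference; 0 gives identical classes.
#' @param margin_transition_mm width of the spectral mixing zone across the
#'   TN interface (mm); 0 gives a hard spectral boundary.
#' @param cohort,modality metadata recorded on generated scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(64, 64),
                       grid = build_band_grid(450, 900, 5),
                       resolution_um_per_px = 100,
                       model = spectral_model(),
                       tumor_geometry = list(center_frac = c(0.45, 0.38),
                                             radius_frac = 0.30,
                                             roughness = 0.25),
                       glare_fraction = 0.02,
                       class_separation = 1,
                       margin_transition_mm = 1,
                       cohort = "conventional",
                       modality = "reflectance") {
  stopifnot(glare_fraction >= 0, glare_fraction <= 0.2, class_separation >= 0,
            margin_transition_mm >= 0, length(image_size) == 2L,
            inherits(grid, "wavelength_grid"), inherits(model, "spectral_model"))
  structure(list(image_size = as.integer(image_size), grid = grid,
                 resolution_um_per_px = resolution_um_per_px, model = model,
                 tumor_geometry = tumor_geometry, glare_fraction = glare_fraction,
                 class_separation = class_separation,
                 margin_transition_mm = margin_transition_mm,
                 cohort = cohort, modality = modality),
            class = "scene_spec")
}

# smooth zero-mean Gaussian random field: low-resolution white noise,
# bilinearly upsampled, rescaled to the requested pointwise sd
smooth_field <- function(h, w, sd, knots = 8) {
  coarse <- matrix(stats::rnorm(knots * knots), knots, knots)
  up <- as.matrix(EBImage::resize(coarse, w = h, h = w))
  up * (sd / stats::sd(as.vector(up)))
}

# irregular blob: ellipse with low-order harmonic boundary modulation,
# drawn from the current RNG stream
blob_mask <- function(h, w, center, radii, roughness, nharm = 3) {
  amp <- roughness * stats::runif(nharm, 0.2, 1) / seq_len(nharm)
  phase <- stats::runif(nharm, 0, 2 * pi)
  di <- outer(seq_len(h) - center[1], rep(1, w))
  dj <- outer(rep(1, h), seq_len(w) - center[2])
  theta <- atan2(dj, di)
  mod <- matrix(1, h, w)
  for (k in seq_len(nharm)) mod <- mod + amp[k] * cos(k * theta + phase[k])
  (di / radii[1])^2 + (dj / radii[2])^2 <= pmax(mod, 0.2)^2
}

#' Draw pixel spectra from the phantom pixel model
#'
#' Samples `n` single-pixel spectra of one class exactly as the scene
#' generator does (mean spectrum x lognormal pixel brightness + per-band
#' Gaussian noise, clamped to the sensor's reflectance headroom). Useful for
#' Monte-Carlo estimates of class overlap.
#'
#' @param spec a [scene_spec()].
#' @param class `"scc"` or `"normal"`.
#' @param n number of pixels.
#' @return an `n x C` matrix.
#' @export
simulate_pixel_spectra <- function(spec, class, n) {
  mu <- class_spectrum(spec$model, class, spec$grid, spec$class_separation)
  pv <- exp(stats::rnorm(n, -spec$model$pixel_variation_sd^2 / 2,
                         spec$model$pixel_variation_sd))
  r <- outer(pv, mu) + matrix(stats::rnorm(n * length(mu), 0, spec$model$noise_sd),
                              n, length(mu))
  pmin(pmax(r, 0), 0.98)
}

# reflectance field for one scene given the tumor-weight field alpha (H x W)
scene_reflectance <- function(spec, alpha, tissue) {
  h <- spec$image_size[1]; w <- spec$image_size[2]; C <- spec$grid$n_bands
  mu_s <- class_spectrum(spec$model, "scc", spec$grid, spec$class_separation)
  mu_n <- class_spectrum(spec$model, "normal", spec$grid, spec$class_separation)
  a <- as.vector(alpha)
  mean_flat <- outer(a, mu_s) + outer(1 - a, mu_n)
  pv <- exp(stats::rnorm(h * w, -spec$model$pixel_variation_sd^2 / 2,
                         spec$model$pixel_variation_sd))
  refl <- mean_flat * pv + matrix(stats::rnorm(h * w * C, 0, spec$model$noise_sd), h * w, C)
  refl[!tissue, ] <- pmax(0.06 + stats::rnorm(sum(!tissue) * C, 0, spec$model$noise_sd / 2), 0)
  refl <- pmin(pmax(refl, 0), 0.98)
  if (spec$glare_fraction > 0 && any(tissue)) {
    n_gl <- round(spec$glare_fraction * sum(tissue))
    if (n_gl > 0) {
      idx <- sample(which(as.vector(tissue)), n_gl)
      refl[idx, ] <- stats::runif(n_gl, 1.02, 1.08) # flat near-saturation spectra
    }
  }
  array(refl, c(h, w, C))
}

scene_frames <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  lambda <- spec$grid$bands
  white_l <- 2200 + 1400 * stats::plogis((lambda - 640) / 120)
  ii <- outer((seq_len(h) - (h + 1) / 2)^2, rep(1, w), "+") +
    outer(rep(1, h), (seq_len(w) - (w + 1) / 2)^2)
  vign <- 1 - 0.12 * ii / max(ii) # mild optical vignetting, undone by calibration
  white <- outer(vign, white_l)
  dark <- array(120, c(h, w, spec$grid$n_bands))
  calibration_frames(dark, array(white, c(h, w, spec$grid$n_bands)))
}

tissue_ellipse <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  center <- c(h, w) / 2 + stats::runif(2, -0.03, 0.03) * c(h, w)
  radii <- c(0.40 * h, 0.42 * w) * stats::runif(2, 0.95, 1.05)
  list(mask = blob_mask(h, w, center, radii, 0.08), center = center, radii = radii)
}

make_one_scene <- function(spec, patient_id, type, seed) {
  with_seed(seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    tis <- tissue_ellipse(spec)
    tissue <- tis$mask
    if (type == "N") {
      tumor <- matrix(FALSE, h, w)
    } else if (type == "T") {
      tumor <- tissue
      u <- (outer(seq_len(h) - tis$center[1], rep(1, w)) / tis$radii[1])^2 +
        (outer(rep(1, h), seq_len(w) - tis$center[2]) / tis$radii[2])^2
      rim <- tissue & u > 0.9 & outer(rep(1, h), seq_len(w) - tis$center[2]) > 0
      if (sum(tissue & !rim) / sum(tissue) >= 0.9) tumor <- tissue & !rim
    } else { # TN: contiguous tumor blob with a single interface
      g <- spec$tumor_geometry
      ok <- FALSE
      for (attempt in 1:10) {
        center <- c(h, w) * g$center_frac + stats::runif(2, -2, 2)
        radius <- g$radius_frac * min(h, w) * stats::runif(1, 0.9, 1.1)
        tumor <- tissue & blob_mask(h, w, center, c(radius, radius), g$roughness)
        ft <- sum(tumor) / sum(tissue)
        if (ft >= 0.1 && ft <= 0.9 && interface_exists(ifelse(tumor, 2L, 1L) * tissue)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) hsim_stop("could not place a TN tumor blob with an interface", "hsim_geometry_error")
    }
    gt <- matrix(0L, h, w)
    gt[tissue] <- 1L
    gt[tumor] <- 2L
    alpha <- matrix(as.numeric(tumor), h, w)
    if (type == "TN" && spec$margin_transition_mm > 0) {
      # The labeled boundary is exact, but the spectral boundary is displaced
      # by a smooth random field (registration / margin-depth uncertainty) and
      # blurred by partial-volume mixing, so near-margin labels genuinely
      # conflict with the underlying spectra.
      w_px <- spec$margin_transition_mm * 1000 / spec$resolution_um_per_px
      din <- as.matrix(EBImage::distmap(matrix(as.numeric(tumor), h, w)))
      dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!tumor), h, w)))
      eta <- smooth_field(h, w, sd = w_px / 2)
      alpha <- stats::plogis(4 * (din - dout + eta) / (w_px / 2))
    }
    refl <- scene_reflectance(spec, alpha, tissue)
    frames <- scene_frames(spec)
    raw <- round(refl * (frames$white - frames$dark) + frames$dark)
    meta <- list(patient_id = patient_id, specimen_type = type,
                 cohort = spec$cohort, modality = spec$modality)
    specimen_scene(hypercube(raw, spec$grid, spec$resolution_um_per_px),
                   frames, gt, meta)
  })
}

interface_exists <- function(gt) {
  nrow(interface_pixels(gt)) > 0
}

#' Generate one phantom patient (T, N, TN triple)
#'
#' Deterministic given `seed`: raw counts are reflectance * (white - dark) +
#' dark plus sensor noise, so [calibrate()] recovers the generating
#' reflectance field up to the noise level.
#'
#' @param spec a [scene_spec()].
#' @param patient_id character id.
#' @param seed integer seed for this patient.
#' @return named list with elements `T`, `N`, `TN` ([specimen_scene()]s).
#' @export
generate_patient <- function(spec, patient_id, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  list(T = make_one_scene(spec, patient_id, "T", derive_seed(seed, 1)),
       N = make_one_scene(spec, patient_id, "N", derive_seed(seed, 2)),
       TN = make_one_scene(spec, patient_id, "TN", derive_seed(seed, 3)))
}

#' Generate a phantom cohort
#'
#' Three scenes (T, N, TN) per patient; per-patient seeds are derived from
#' the master seed by a counter scheme so cohorts are reproducible.
#'
#' @param n_patients number of patients (>= 5 for fold experiments).
#' @param spec a [scene_spec()].
#' @param seed master seed.
#' @param out_dir optional directory; when given, scenes are written as ENVI
#'   scene directories and a `manifest.csv` is created.
#' @return an object of class `phantom_cohort`: list with `scenes` (named by
#'   `<patient>_<type>`), `manifest` (data.frame) and `spec`.
#' @export
generate_cohort <- function(n_patients, spec = scene_spec(), seed = 1, out_dir = NULL) {
  stopifnot(n_patients >= 1)
  scenes <- list()
  rows <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    triple <- generate_patient(spec, pid, derive_seed(seed, i))
    for (type in names(triple)) {
      sc <- triple[[type]]
      id <- scene_id(sc)
      scenes[[id]] <- sc
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, id)
        write_scene(sc, path)
      }
      rows[[id]] <- data.frame(patient_id = pid, scene_id = id,
                               specimen_type = type, cohort = spec$cohort,
                               modality = spec$modality, path = path,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(scenes = scenes, manifest = manifest, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, %d scenes, modality %s\n",
              length(unique(x$manifest$patient_id)), nrow(x$manifest),
              x$spec$modality))
  invisible(x)
}
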