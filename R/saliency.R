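minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(v * 0)
  (v - rng[1]) / (rng[2] - rng[1])
}

# Per-patch per-band statistics for one patch set: spatial means of the
# class-score gradient at the input and of the standardized input, either
# uniform over the window or weighted by the grad-CAM map of the target
# class taken at the last inception block.
gradcam_patch_stats <- function(model, xn, idx, target_sign, batch, weighting) {
  C <- dim(xn)[4]
  grad_patch <- matrix(0, length(idx), C)
  input_patch <- matrix(0, length(idx), C)
  at <- 0L
  for (start in seq(1, length(idx), by = batch)) {
    bi <- idx[start:min(start + batch - 1, length(idx))]
    xb <- xn[bi, , , , drop = FALSE]
    m <- length(bi)
    fw <- cnn_forward(xb, model$params, keep_cache = TRUE)
    bk <- cnn_backward(rep(target_sign, m), model$params, fw$cache)
    h <- dim(xb)[2]; w <- dim(xb)[3]
    if (weighting == "gradcam") {
      a <- fw$cache$a_last
      g <- bk$d_a_last
      f <- dim(a)[4]
      g_flat <- matrix(g, m, h * w * f)
      a_flat <- matrix(a, m, h * w * f)
      cam <- matrix(0, m, h * w)
      for (k in seq_len(f)) {
        cols <- ((k - 1) * h * w + 1):(k * h * w)
        cam <- cam + rowMeans(g_flat[, cols, drop = FALSE]) *
          a_flat[, cols, drop = FALSE]
      }
      cam <- pmax(cam, 0)
      cam_sum <- rowSums(cam)
      cam <- cam / ifelse(cam_sum > 0, cam_sum, h * w)
      cam[cam_sum == 0, ] <- 1 / (h * w) # zero CAM -> uniform weights
    } else {
      cam <- matrix(1 / (h * w), m, h * w)
    }
    g_in <- matrix(bk$dx, m, h * w * C)
    x_in <- matrix(xb, m, h * w * C)
    for (b in seq_len(C)) {
      cols <- ((b - 1) * h * w + 1):(b * h * w)
      grad_patch[at + seq_len(m), b] <- rowSums(cam * g_in[, cols, drop = FALSE])
      input_patch[at + seq_len(m), b] <- rowSums(cam * x_in[, cols, drop = FALSE])
    }
    at <- at + m
  }
  list(grad = grad_patch, input = input_patch)
}

#' Grad-CAM spectral saliency profile
#'
#' Per-wavelength importance of the trained patch classifier for one class,
#' from class-activated gradients, with the input's spectral bands playing
#' the role of grad-CAM channels. Per band, the channel weight (spatial
#' mean of the class-score gradient at the input, averaged over the
#' correctly classified patches of the target class, as grad-CAM pools its
#' channel weights) is multiplied by the channel activation (the same
#' average of the standardized input), and the profile is the rectified
#' product, min-max scaled to \[0, 1\].
#'
#' When correctly classified patches of the *other* class are present in
#' `patches`, the activation term is centered on the pooled mean over both
#' classes. Centering makes class-independent structure —
#' tissue-vs-background offsets, the shared pixel-brightness field — cancel
#' exactly, so bands the network merely uses for normalization (pure
#' sensitivity) cannot dominate bands that carry class contrast. For the
#' same reason activations are averaged over patches *before* the product.
#' `spatial_weighting = "gradcam"` additionally weights the spatial means
#' by the grad-CAM map of the target class at the last inception block;
#' the uniform default is more robust on phantoms because CAM weights do
#' not cancel between the two classes' patch sets. Profiles are meaningful
#' for fully trained networks; an under-trained network's gradients still
#' reflect its random initialization.
#'
#' @param model a trained [train_fold()] `patch_cnn`.
#' @param patches m x h x w x C array (or list with `patches`), ideally
#'   containing both classes so the activation term can be centered.
#' @param labels 0/1 ground-truth patch labels (1 = SCC).
#' @param target_class `"scc"` or `"normal"`.
#' @param spatial_weighting `"uniform"` (default) or `"gradcam"`.
#' @param batch internal batch size.
#' @return an object of class `saliency_profile`: `wavelengths`, `saliency`
#'   (per band, in \[0, 1\], max 1 unless identically zero), `per_patch_grad`
#'   and `per_patch_input` (per-patch spatial-mean statistics), `class`,
#'   `n_patches`, `flagged_zero`.
#' @export
gradcam_spectral <- function(model, patches, labels, target_class = c("scc", "normal"),
                             spatial_weighting = c("uniform", "gradcam"),
                             batch = 64L) {
  target_class <- match.arg(target_class)
  spatial_weighting <- match.arg(spatial_weighting)
  stopifnot(inherits(model, "patch_cnn"))
  x <- if (is.list(patches)) patches$patches else patches
  labels <- as.integer(if (is.list(patches) && missing(labels)) patches$labels else labels)
  stopifnot(length(dim(x)) == 4L, dim(x)[1] == length(labels))
  xn <- normalize_patches(x, model$band_mean, model$band_sd)
  probs <- cnn_predict_raw(model$params, xn)
  want <- if (target_class == "scc") 1L else 0L
  correct <- labels == as.integer(probs >= 0.5)
  sel <- which(correct & labels == want)
  other <- which(correct & labels != want)
  if (!length(sel)) {
    hsim_stop(sprintf("no correctly classified %s patches to attribute", target_class),
              "hsim_no_examples")
  }
  sign <- if (target_class == "scc") 1 else -1
  stats <- gradcam_patch_stats(model, xn, sel, sign, batch, spatial_weighting)
  alpha <- colMeans(stats$grad)
  activation <- colMeans(stats$input)
  if (length(other)) {
    stats_other <- gradcam_patch_stats(model, xn, other, sign, batch, spatial_weighting)
    pooled <- colMeans(rbind(stats$input, stats_other$input))
    activation <- activation - pooled
  }
  saliency <- minmax_scale(pmax(alpha * activation, 0))
  flagged <- all(saliency == 0)
  if (flagged) {
    hsim_warn("all-zero saliency profile (constant-output model?)", "hsim_zero_saliency")
  }
  wl <- model$wavelengths
  if (is.null(wl)) wl <- seq_len(dim(x)[4])
  structure(list(wavelengths = wl, saliency = as.vector(saliency),
                 per_patch_grad = stats$grad, per_patch_input = stats$input,
                 class = target_class, n_patches = length(sel),
                 flagged_zero = flagged),
            class = "saliency_profile")
}

#' @export
print.saliency_profile <- function(x, ...) {
  top <- order(x$saliency, decreasing = TRUE)[1:min(3, length(x$saliency))]
  cat(sprintf("<saliency_profile> class %s, %d patches; top bands: %s nm\n",
              x$class, x$n_patches, paste(x$wavelengths[top], collapse = ", ")))
  invisible(x)
}

#' @export
plot.saliency_profile <- function(x, ...) {
  graphics::plot(x$wavelengths, x$saliency, type = "h", lwd = 2,
                 xlab = "Wavelength (nm)", ylab = "Scaled saliency", ylim = c(0, 1), ...)
  invisible(x)
}
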