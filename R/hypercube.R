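#' Build a regular wavelength grid
#'
#' Constructs the band grid of a hyperspectral acquisition: centers from
#' `start_nm` to `stop_nm` in steps of `step_nm`. The reflectance modality
#' used throughout the package spans 450-900 nm in 5 nm steps (91 bands);
#' fluorescence modalities span 500-720 nm in 10 nm steps (23 bands).
#'
#' @param start_nm first band center (nm).
#' @param stop_nm last band center (nm); `step_nm` must divide
#'   `stop_nm - start_nm` exactly.
#' @param step_nm band spacing (nm), > 0.
#' @return an object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm`, `bands` (band centers, strictly increasing) and
#'   `n_bands`.
#' @examples
#' build_band_grid(450, 900, 5)$n_bands  # 91
#' build_band_grid(500, 720, 10)$n_bands # 23
#' @export
build_band_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is_scalar_number(start_nm), is_scalar_number(stop_nm), is_scalar_number(step_nm))
  if (step_nm <= 0 || start_nm > stop_nm) {
    hsim_stop(sprintf("invalid band grid (%g, %g, %g): need step > 0 and start <= stop",
                      start_nm, stop_nm, step_nm), "hsim_grid_error")
  }
  k <- (stop_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8) {
    hsim_stop(sprintf("step %g nm does not divide the range %g-%g nm exactly",
                      step_nm, start_nm, stop_nm), "hsim_grid_error")
  }
  k <- round(k)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         bands = start_nm + step_nm * (0:k), n_bands = k + 1L),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, %g nm steps, %d bands\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n_bands))
  invisible(x)
}

#' Hyperspectral cube
#'
#' A 3D raster (rows x cols x bands) bound to a wavelength grid. Values are
#' raw sensor counts before calibration and dimensionless reflectance after.
#' Reflectance above 1 (specular glare) is legal and retained.
#'
#' @param values numeric H x W x C array, nonnegative.
#' @param grid a [build_band_grid()] object; `C` must equal `grid$n_bands`.
#' @param resolution_um_per_px spatial sampling (micrometres per pixel).
#' @param flagged optional H x W logical matrix of pixels whose calibration
#'   was unreliable (nonpositive white-minus-dark denominator).
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(values, grid, resolution_um_per_px = 25, flagged = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            inherits(grid, "wavelength_grid"))
  if (dim(values)[3] != grid$n_bands) {
    hsim_stop(sprintf("cube has %d bands but grid lists %d wavelengths",
                      dim(values)[3], grid$n_bands), "hsim_format_error")
  }
  if (!is_scalar_number(resolution_um_per_px) || resolution_um_per_px <= 0) {
    hsim_stop("resolution_um_per_px must be a positive number", "hsim_format_error")
  }
  if (min(values, na.rm = TRUE) < -1e-9) {
    hsim_stop("hypercube values must be nonnegative", "hsim_format_error")
  }
  structure(list(values = values, grid = grid,
                 resolution_um_per_px = resolution_um_per_px, flagged = flagged),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%g-%g nm), %g um/px\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm,
              x$resolution_um_per_px))
  invisible(x)
}

#' Dark-current and white-reference calibration frames
#'
#' @param dark H x W x C raw counts imaged with a closed shutter.
#' @param white H x W x C raw counts of a white reference disk.
#' @return an object of class `calibration_frames`.
#' @export
calibration_frames <- function(dark, white) {
  stopifnot(is.array(dark), is.array(white), length(dim(dark)) == 3L)
  if (!identical(dim(dark), dim(white))) {
    hsim_stop("dark and white frames have different shapes", "hsim_format_error")
  }
  structure(list(dark = dark, white = white), class = "calibration_frames")
}

#' Calibrate raw counts to normalized reflectance
#'
#' Per-band flat-field normalization: `(raw - dark) / (white - dark)`
#' (default), or `(raw - dark) / white` for instruments whose white
#' normalization was not dark-subtracted. Pixels where the denominator is
#' nonpositive in any band are set to `NA` and returned in the `flagged`
#' matrix of the result rather than propagating silent NaNs. Negative
#' numerators (shot noise below the dark level) are clamped to zero; values
#' above 1 (specular glare) are retained unless `clip = TRUE`, which is
#' intended for visualization only.
#'
#' @param raw a raw-count [hypercube()].
#' @param frames a [calibration_frames()] object of matching shape.
#' @param denominator `"range"` for white - dark (default), `"white"` for the
#'   non-dark-subtracted convention.
#' @param clip clamp reflectance into \[0, 1\]? Default `FALSE`.
#' @return a reflectance `hypercube` carrying a `flagged` H x W logical matrix.
#' @export
calibrate <- function(raw, frames, denominator = c("range", "white"), clip = FALSE) {
  stopifnot(inherits(raw, "hypercube"), inherits(frames, "calibration_frames"))
  denominator <- match.arg(denominator)
  if (!identical(dim(raw$values), dim(frames$dark))) {
    hsim_stop("raw cube and calibration frames have different shapes", "hsim_format_error")
  }
  den <- if (denominator == "range") frames$white - frames$dark else frames$white
  bad <- den <= 0
  den[bad] <- 1 # placeholder; flagged below
  refl <- (raw$values - frames$dark) / den
  refl[refl < 0] <- 0
  if (clip) refl[refl > 1] <- 1
  flagged <- apply(bad, c(1, 2), any)
  if (any(flagged)) {
    refl[array(rep(flagged, dim(refl)[3]), dim(refl))] <- NA_real_
  }
  hypercube(refl, raw$grid, raw$resolution_um_per_px, flagged = flagged)
}

#' Synthesize an RGB composite from a calibrated cube
#'
#' Each color channel is a convex Gaussian-weighted average of the spectral
#' bands around a channel center, mirroring how display composites are made
#' from visible-range hypercubes. Weights are `exp(-(lambda - center)^2 /
#' (2 sigma^2))`, normalized to sum to one per channel; `sigma = 0` degenerates
#' to picking the single band at the center.
#'
#' @param cube calibrated [hypercube()].
#' @param centers_nm three channel centers (R, G, B order), each inside the
#'   grid range. Defaults 650/550/450 nm.
#' @param sigmas_nm three kernel widths (nm), default 30.
#' @param clip clamp channels into \[0, 1\] (glare can push convex averages
#'   above 1)? Default `TRUE`.
#' @return an object of class `rgb_composite` with fields `values`
#'   (H x W x 3), `kernel_centers_nm`, `kernel_sigmas_nm`.
#' @export
make_rgb <- function(cube, centers_nm = c(650, 550, 450), sigmas_nm = c(30, 30, 30),
                     clip = TRUE) {
  stopifnot(inherits(cube, "hypercube"), length(centers_nm) == 3L, length(sigmas_nm) == 3L)
  bands <- cube$grid$bands
  if (any(centers_nm < min(bands)) || any(centers_nm > max(bands))) {
    hsim_stop("RGB kernel center outside the wavelength grid range", "hsim_grid_error")
  }
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    if (sigmas_nm[ch] <= .Machine$double.eps) {
      hit <- which(abs(bands - centers_nm[ch]) < 1e-9)
      if (length(hit) != 1L) {
        hsim_stop("sigma = 0 requires the channel center to sit exactly on a grid band",
                  "hsim_grid_error")
      }
      w <- numeric(length(bands)); w[hit] <- 1
    } else {
      w <- exp(-(bands - centers_nm[ch])^2 / (2 * sigmas_nm[ch]^2))
      w <- w / sum(w)
    }
    out[, , ch] <- matrix(flat %*% w, d[1], d[2])
  }
  if (clip) {
    out[out > 1] <- 1
    out[out < 0] <- 0
  }
  structure(list(values = out, kernel_centers_nm = centers_nm,
                 kernel_sigmas_nm = sigmas_nm),
            class = "rgb_composite")
}

# separable Chebyshev (square structuring element) erosion; pixels beyond the
# image border count as background, so tissue touching the frame is trimmed too.
erode_1d <- function(m, n, dim) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (o in seq_len(n)) {
    if (dim == 1L) {
      up <- rbind(m[-seq_len(o), , drop = FALSE], matrix(FALSE, o, nc))
      dn <- rbind(matrix(FALSE, o, nc), m[seq_len(nr - o), , drop = FALSE])
    } else {
      up <- cbind(m[, -seq_len(o), drop = FALSE], matrix(FALSE, nr, o))
      dn <- cbind(matrix(FALSE, nr, o), m[, seq_len(nc - o), drop = FALSE])
    }
    out <- out & up & dn
  }
  out
}

#' Trim unreliable tissue edges
#'
#' Erodes a binary tissue mask by `n_pixels` with a square (Chebyshev)
#' structuring element of that radius. Tissue free edges curve away from the
#' imaging surface and yield too little signal, so a rim (10 px = 0.25 mm at
#' 25 um/px) is discarded from all downstream performance calculations.
#'
#' @param tissue_mask logical H x W matrix (TRUE = tissue).
#' @param n_pixels erosion radius in pixels, >= 0.
#' @return the eroded logical matrix. An all-FALSE result is allowed but
#'   raises a warning.
#' @export
trim_tissue_edge <- function(tissue_mask, n_pixels) {
  stopifnot(is.matrix(tissue_mask), is_scalar_number(n_pixels), n_pixels >= 0)
  mode(tissue_mask) <- "logical"
  n_pixels <- as.integer(n_pixels)
  if (n_pixels == 0L) return(tissue_mask)
  out <- erode_1d(erode_1d(tissue_mask, n_pixels, 1L), n_pixels, 2L)
  if (!any(out) && any(tissue_mask)) {
    hsim_warn("edge trim removed every tissue pixel", "hsim_empty_mask")
  }
  out
}
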