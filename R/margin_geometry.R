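# core: tissue pixels having a 4-neighbor of the opposite tissue class;
# returns a (possibly empty) n x 2 matrix of (row, col)
interface_pixels <- function(gt_mask) {
  h <- nrow(gt_mask); w <- ncol(gt_mask)
  tumor <- gt_mask == 2L
  normal <- gt_mask == 1L
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    keep_r <- rs >= 1 & rs <= h; keep_c <- cs >= 1 & cs <= w
    out[rs[keep_r], cs[keep_c]] <- m[which(keep_r), which(keep_c)]
    out
  }
  opp_near <- function(m, other) {
    m & (shift(other, 1, 0) | shift(other, -1, 0) | shift(other, 0, 1) | shift(other, 0, -1))
  }
  on_iface <- opp_near(tumor, normal) | opp_near(normal, tumor)
  which(on_iface, arr.ind = TRUE)
}

#' Find the tumor-normal interface
#'
#' Returns the pixels that comprise the interface of tumor and normal: tissue
#' pixels with at least one 4-neighbor of the opposite tissue class (both
#' sides of the boundary are returned). Background is ignored.
#'
#' @param gt_mask integer H x W label mask (0 background, 1 normal, 2 tumor).
#' @return an n x 2 matrix of (row, col) coordinates.
#' @export
find_interface <- function(gt_mask) {
  stopifnot(is.matrix(gt_mask))
  if (!any(gt_mask == 1L) || !any(gt_mask == 2L)) {
    hsim_stop("mask contains a single tissue class; no tumor-normal interface exists",
              "hsim_no_interface")
  }
  interface_pixels(gt_mask)
}

#' Distance-to-margin map
#'
#' Exact Euclidean distance from every tissue pixel to the nearest interface
#' pixel, converted to millimetres via the spatial resolution (at 25 um/px,
#' 40 px correspond to 1 mm). Background pixels carry `NA`.
#'
#' @param gt_mask integer H x W label mask containing both tissue classes.
#' @param resolution_um_per_px spatial scale (um/pixel).
#' @return an object of class `distance_map`: list with `values_mm` (H x W,
#'   `NA` on background), `interface` (coordinates) and
#'   `resolution_um_per_px`.
#' @export
distance_to_margin <- function(gt_mask, resolution_um_per_px = 25) {
  iface <- find_interface(gt_mask)
  img <- matrix(1, nrow(gt_mask), ncol(gt_mask))
  img[iface] <- 0
  d_px <- as.matrix(EBImage::distmap(img, metric = "euclidean"))
  values <- d_px * resolution_um_per_px / 1000
  values[gt_mask == 0L] <- NA_real_
  structure(list(values_mm = values, interface = iface,
                 resolution_um_per_px = resolution_um_per_px),
            class = "distance_map")
}

#' Millimeter-increment evaluation mask
#'
#' Builds the pixel set over which performance at margin distance `d` is
#' computed. In the default `"exclude"` reading, pixels within `d` mm of the
#' tumor-normal interface are removed (on both sides) and metrics are
#' computed on the remainder, so `d = 0` ("actual TN") keeps every trimmed
#' tissue pixel and masks are nested: larger `d` always gives a subset. The
#' `"include"` reading (pixels at distance <= d) is available for sensitivity
#' analysis.
#'
#' @param distmap a [distance_to_margin()] object.
#' @param d_mm margin distance threshold (mm), >= 0.
#' @param tissue_mask logical H x W mask of pixels eligible for evaluation
#'   (typically the edge-trimmed tissue mask).
#' @param mode `"exclude"` (default) or `"include"`.
#' @return an object of class `evaluation_mask`: list with `distance_mm`,
#'   `included` (logical H x W) and `mode`.
#' @export
exclusion_mask <- function(distmap, d_mm, tissue_mask, mode = c("exclude", "include")) {
  stopifnot(inherits(distmap, "distance_map"), d_mm >= 0, is.matrix(tissue_mask))
  mode <- match.arg(mode)
  d <- distmap$values_mm
  sel <- if (mode == "exclude") !is.na(d) & d >= d_mm else !is.na(d) & d <= d_mm
  included <- tissue_mask & sel
  if (!any(included)) {
    hsim_warn(sprintf("no pixels remain at margin distance %g mm; metrics undefined", d_mm),
              "hsim_empty_mask")
  }
  structure(list(distance_mm = d_mm, included = included, mode = mode),
            class = "evaluation_mask")
}
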