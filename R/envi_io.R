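# Minimal ENVI raster dialect: a text .hdr describing a headerless binary
# data file. Supported: data types 1 (uint8), 4 (float32), 5 (float64);
# interleaves bsq/bil/bip; little-endian (byte order 0). Cubes carry their
# band centers in the `wavelength` header field.

envi_data_paths <- function(path) {
  base <- sub("\\.hdr$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".img"))
}

#' Write an array as an ENVI raster
#'
#' @param values H x W (single band) or H x W x C numeric array.
#' @param path output path; `.hdr` and `.img` extensions are appended to its
#'   base name.
#' @param wavelength optional numeric vector of band centers (nm), length C.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 1 (byte), 4 (float32) or 5 (float64).
#' @return the `.hdr` path, invisibly.
#' @export
write_envi <- function(values, path, wavelength = NULL,
                       interleave = c("bsq", "bil", "bip"), data_type = 5) {
  interleave <- match.arg(interleave)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L, data_type %in% c(1, 4, 5))
  d <- dim(values) # lines (H), samples (W), bands
  if (!is.null(wavelength) && length(wavelength) != d[3]) {
    hsim_stop("wavelength metadata length does not match band count", "hsim_format_error")
  }
  p <- envi_data_paths(path)
  # ENVI order: sample fastest, then line/band per interleave
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))
  vec <- as.vector(aperm(values, perm))
  con <- file(p$dat, "wb")
  on.exit(close(con))
  if (data_type == 1) {
    writeBin(as.raw(as.integer(round(vec))), con)
  } else {
    writeBin(as.double(vec), con, size = if (data_type == 4) 4L else 8L,
             endian = "little")
  }
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0")
  if (!is.null(wavelength)) {
    hdr <- c(hdr, paste0("wavelength = {", paste(format(wavelength, trim = TRUE),
                                                 collapse = ", "), "}"))
  }
  writeLines(hdr, p$hdr)
  invisible(p$hdr)
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(joined, regexpr(sprintf("%s\\s*=\\s*[0-9]+", key), joined))
    if (!length(m)) hsim_stop(sprintf("ENVI header missing '%s'", key), "hsim_format_error")
    as.integer(sub(".*=\\s*", "", m))
  }
  get_str <- function(key, default = NULL) {
    m <- regmatches(joined, regexpr(sprintf("%s\\s*=\\s*[a-zA-Z]+", key), joined))
    if (!length(m)) return(default)
    tolower(sub(".*=\\s*", "", m))
  }
  wl <- NULL
  m <- regmatches(joined, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", joined))
  if (length(m)) {
    wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  }
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = get_str("interleave", "bsq"),
       byte_order = get_num("byte order"), wavelength = wl)
}

#' Read an ENVI raster
#'
#' @param path path to the `.hdr` file (or its base name).
#' @return a list with `values` (H x W x C array) and `wavelength`
#'   (numeric or NULL).
#' @export
read_envi <- function(path) {
  p <- envi_data_paths(path)
  if (!file.exists(p$hdr)) hsim_stop(paste("no ENVI header at", p$hdr), "hsim_format_error")
  h <- parse_envi_header(p$hdr)
  n <- h$samples * h$lines * h$bands
  con <- file(p$dat, "rb")
  on.exit(close(con))
  vec <- if (h$data_type == 1) {
    as.numeric(readBin(con, "raw", n))
  } else if (h$data_type %in% c(4, 5)) {
    readBin(con, "double", n, size = if (h$data_type == 4) 4L else 8L,
            endian = "little")
  } else {
    hsim_stop(sprintf("unsupported ENVI data type %d", h$data_type), "hsim_format_error")
  }
  if (length(vec) != n) {
    hsim_stop("ENVI data file shorter than header dimensions imply", "hsim_format_error")
  }
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines))
  perm <- switch(h$interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2), bip = c(3, 2, 1))
  values <- aperm(array(vec, dims), perm)
  if (!is.null(h$wavelength) && length(h$wavelength) != h$bands) {
    hsim_stop(sprintf("ENVI header lists %d wavelengths for %d bands",
                      length(h$wavelength), h$bands), "hsim_format_error")
  }
  list(values = values, wavelength = h$wavelength)
}

#' Specimen scene
#'
#' One specimen's raw hypercube, its calibration frames, the registered
#' ground-truth label mask (0 = background, 1 = normal, 2 = tumor) and
#' specimen metadata.
#'
#' @param raw raw-count [hypercube()].
#' @param frames [calibration_frames()].
#' @param gt_mask integer H x W matrix with codes 0/1/2.
#' @param meta list with `patient_id`, `specimen_type` (`"T"`, `"N"`, `"TN"`),
#'   `cohort` (`"conventional"` or `"hpv_pos"`) and `modality`.
#' @return an object of class `specimen_scene`; `tissue_mask` is derived as
#'   `gt_mask > 0`.
#' @export
specimen_scene <- function(raw, frames, gt_mask, meta) {
  stopifnot(inherits(raw, "hypercube"), inherits(frames, "calibration_frames"),
            is.matrix(gt_mask))
  if (!all(gt_mask %in% 0:2)) {
    hsim_stop("gt_mask codes must be 0 (background), 1 (normal) or 2 (tumor)",
              "hsim_format_error")
  }
  need <- c("patient_id", "specimen_type", "cohort", "modality")
  if (!all(need %in% names(meta))) {
    hsim_stop(paste("scene metadata must include", paste(need, collapse = ", ")),
              "hsim_format_error")
  }
  if (!meta$specimen_type %in% c("T", "N", "TN")) {
    hsim_stop("specimen_type must be one of T, N, TN", "hsim_format_error")
  }
  storage.mode(gt_mask) <- "integer"
  structure(list(raw = raw, frames = frames, gt_mask = gt_mask,
                 tissue_mask = gt_mask > 0L, meta = meta),
            class = "specimen_scene")
}

#' @export
print.specimen_scene <- function(x, ...) {
  d <- dim(x$raw$values)
  cat(sprintf("<specimen_scene> patient %s, type %s, %s/%s, %dx%d px, %d bands\n",
              x$meta$patient_id, x$meta$specimen_type, x$meta$cohort,
              x$meta$modality, d[1], d[2], d[3]))
  invisible(x)
}

scene_id <- function(scene) paste(scene$meta$patient_id, scene$meta$specimen_type, sep = "_")

#' Write / read a specimen scene directory
#'
#' A scene directory holds `raw`, `dark`, `white` (float64 ENVI cubes with
#' wavelength metadata), `mask` (byte ENVI raster) and `meta.yaml`. The
#' round trip is lossless for values, wavelengths, labels and metadata.
#'
#' @param scene a [specimen_scene()].
#' @param dir directory to create/read.
#' @return `write_scene` returns `dir` invisibly; `read_scene` returns a
#'   `specimen_scene`.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "specimen_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- scene$raw$grid$bands
  write_envi(scene$raw$values, file.path(dir, "raw"), wavelength = wl)
  write_envi(scene$frames$dark, file.path(dir, "dark"), wavelength = wl)
  write_envi(scene$frames$white, file.path(dir, "white"), wavelength = wl)
  write_envi(scene$gt_mask, file.path(dir, "mask"), data_type = 1)
  meta <- scene$meta
  meta$resolution_um_per_px <- scene$raw$resolution_um_per_px
  meta$grid <- list(start_nm = scene$raw$grid$start_nm,
                    stop_nm = scene$raw$grid$stop_nm,
                    step_nm = scene$raw$grid$step_nm)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  grid <- build_band_grid(meta$grid$start_nm, meta$grid$stop_nm, meta$grid$step_nm)
  raw <- read_envi(file.path(dir, "raw"))
  if (is.null(raw$wavelength)) {
    hsim_stop("raw cube lacks wavelength metadata", "hsim_format_error")
  }
  if (length(raw$wavelength) != grid$n_bands ||
      max(abs(raw$wavelength - grid$bands)) > 1e-6) {
    hsim_stop("wavelength metadata inconsistent with the scene's band grid",
              "hsim_format_error")
  }
  res <- meta$resolution_um_per_px
  dark <- read_envi(file.path(dir, "dark"))$values
  white <- read_envi(file.path(dir, "white"))$values
  mask <- read_envi(file.path(dir, "mask"))$values[, , 1]
  meta$resolution_um_per_px <- NULL
  meta$grid <- NULL
  specimen_scene(hypercube(raw$values, grid, res),
                 calibration_frames(dark, white), mask, meta)
}
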