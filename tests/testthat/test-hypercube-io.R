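test_that("band grids match the instrument protocols and enumerate correctly", {
  expect_equal(build_band_grid(450, 900, 5)$n_bands, 91L)
  expect_equal(build_band_grid(500, 720, 10)$n_bands, 23L)
  g1 <- build_band_grid(450, 450, 5)
  expect_equal(g1$n_bands, 1L)
  expect_equal(g1$bands, 450)
  expect_error(build_band_grid(450, 902, 5), class = "hsim_grid_error")
  expect_error(build_band_grid(900, 450, 5), class = "hsim_grid_error")
  # brute-force enumeration of the arithmetic sequence for random valid triples
  set.seed(11)
  for (i in 1:200) {
    start <- sample(200:800, 1)
    step <- sample(1:25, 1)
    k <- sample(0:60, 1)
    g <- build_band_grid(start, start + k * step, step)
    seq_bf <- c()
    x <- start
    while (x <= start + k * step + 1e-9) {
      seq_bf <- c(seq_bf, x)
      x <- x + step
    }
    expect_equal(g$n_bands, length(seq_bf))
    expect_equal(g$bands, seq_bf)
    expect_true(all(diff(g$bands) > 0))
  }
})

test_that("calibration implements flat-field normalization with flagging", {
  g <- build_band_grid(450, 470, 10)
  dims <- c(4, 4, 3)
  dark <- array(10, dims)
  white <- array(110, dims)
  frames <- calibration_frames(dark, white)
  # raw = white -> all ones; raw = dark -> all zeros
  expect_equal(calibrate(hypercube(white, g), frames)$values, array(1, dims))
  expect_equal(calibrate(hypercube(dark, g), frames)$values, array(0, dims))
  # hand arithmetic: (5 - 1)/(9 - 1) = 0.5
  f2 <- calibration_frames(array(1, dims), array(9, dims))
  raw <- array(5, dims)
  expect_equal(calibrate(hypercube(raw, g), f2)$values[2, 3, 1], 0.5)
  # alternative white-only denominator: (5 - 1)/9
  expect_equal(calibrate(hypercube(raw, g), f2, denominator = "white")$values[1, 1, 1], 4 / 9)
  # affine invariance: a * white + (1 - a) * dark -> a, elementwise
  for (a in c(0, 0.25, 0.6, 1)) {
    mix <- a * white + (1 - a) * dark
    expect_equal(calibrate(hypercube(mix, g), frames)$values, array(a, dims))
  }
  # nonpositive denominator -> flagged pixels, NA values, no silent NaN
  bad_white <- white
  bad_white[2, 2, ] <- 5 # below dark
  cal <- calibrate(hypercube(raw, g), calibration_frames(dark, bad_white))
  expect_true(cal$flagged[2, 2])
  expect_equal(sum(cal$flagged), 1L)
  expect_true(all(is.na(cal$values[2, 2, ])))
  expect_false(anyNA(cal$values[1, , ]))
  # shape mismatch
  expect_error(calibrate(hypercube(array(1, c(3, 4, 3)), g), frames),
               class = "hsim_format_error")
})

test_that("glare above the white reference is retained unless clipped", {
  g <- build_band_grid(450, 470, 10)
  dims <- c(2, 2, 3)
  frames <- calibration_frames(array(0, dims), array(100, dims))
  raw <- hypercube(array(130, dims), g)
  expect_equal(calibrate(raw, frames)$values[1, 1, 1], 1.3)
  expect_equal(calibrate(raw, frames, clip = TRUE)$values[1, 1, 1], 1)
})

test_that("RGB composites are convex band averages", {
  g <- build_band_grid(450, 650, 100) # 3 bands: 450, 550, 650
  vals <- array(0, c(2, 2, 3))
  vals[, , 1] <- 0.2; vals[, , 2] <- 0.5; vals[, , 3] <- 0.8
  cube <- hypercube(vals, g)
  # brute-force weighted-sum oracle with hand-evaluated Gaussian weights
  centers <- c(650, 550, 450); sigma <- 60
  rgb <- make_rgb(cube, centers, rep(sigma, 3), clip = FALSE)
  for (ch in 1:3) {
    w <- exp(-(g$bands - centers[ch])^2 / (2 * sigma^2))
    w <- w / sum(w)
    expected <- sum(w * c(0.2, 0.5, 0.8))
    expect_equal(rgb$values[1, 1, ch], expected)
  }
  # constant cube -> constant composite
  cube_c <- hypercube(array(0.37, c(2, 2, 3)), g)
  expect_equal(make_rgb(cube_c, centers, rep(30, 3))$values, array(0.37, c(2, 2, 3)))
  # sigma -> 0 picks the single band at the center
  rgb0 <- make_rgb(cube, c(650, 550, 450), c(0, 0, 0), clip = FALSE)
  expect_equal(rgb0$values[1, 1, ], c(0.8, 0.5, 0.2))
  # convexity: channels within the band range of the cube
  set.seed(3)
  vr <- array(runif(2 * 2 * 3), c(2, 2, 3))
  rr <- make_rgb(hypercube(vr, g), centers, rep(40, 3), clip = FALSE)
  for (i in 1:2) for (j in 1:2) {
    expect_true(all(rr$values[i, j, ] >= min(vr[i, j, ]) - 1e-12))
    expect_true(all(rr$values[i, j, ] <= max(vr[i, j, ]) + 1e-12))
  }
  expect_error(make_rgb(cube, c(900, 550, 450)), class = "hsim_grid_error")
})

test_that("edge trim erodes with a square structuring element", {
  solid <- matrix(TRUE, 30, 30)
  expect_identical(trim_tissue_edge(solid, 0), solid)
  tr <- trim_tissue_edge(solid, 10)
  expect_equal(sum(tr), 100)
  expect_true(all(tr[11:20, 11:20]))
  # brute-force pixel-window oracle on random masks
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(20 * 16) > 0.3, 20, 16)
    n <- sample(1:3, 1)
    expect_identical(suppressWarnings(trim_tissue_edge(m, n)), erode_oracle(m, n))
  }
  # semigroup property: erode(erode(m, a), b) = erode(m, a + b)
  m <- matrix(runif(30 * 30) > 0.05, 30, 30)
  expect_identical(suppressWarnings(trim_tissue_edge(trim_tissue_edge(m, 2), 3)),
                   suppressWarnings(trim_tissue_edge(m, 5)))
  # thin mask fully eroded, with warning
  thin <- matrix(FALSE, 10, 10); thin[5:6, ] <- TRUE
  expect_warning(res <- trim_tissue_edge(thin, 2), class = "hsim_empty_mask")
  expect_false(any(res))
})

test_that("ENVI round trips are lossless and interleaves agree", {
  cube <- index_cube(6, 5)
  base <- file.path(tempdir(), "cube_rt")
  write_envi(cube$values, base, wavelength = cube$grid$bands)
  back <- read_envi(base)
  expect_identical(back$values, cube$values)
  expect_equal(back$wavelength, cube$grid$bands)
  # all interleaves load to identical arrays; BSQ checked against an
  # independent base-R reader of the raw stream
  for (il in c("bsq", "bil", "bip")) {
    p <- file.path(tempdir(), paste0("cube_", il))
    write_envi(cube$values, p, wavelength = cube$grid$bands, interleave = il)
    expect_identical(read_envi(p)$values, cube$values, label = il)
  }
  d <- dim(cube$values)
  con <- file(file.path(tempdir(), "cube_bsq.img"), "rb")
  raw_vec <- readBin(con, "double", prod(d), size = 8, endian = "little")
  close(con)
  ref <- aperm(array(raw_vec, c(d[2], d[1], d[3])), c(2, 1, 3))
  expect_identical(ref, cube$values)
  # wavelength metadata inconsistent with band count
  expect_error(write_envi(cube$values, file.path(tempdir(), "bad"),
                          wavelength = cube$grid$bands[1:3]),
               class = "hsim_format_error")
  hdr <- readLines(paste0(base, ".hdr"))
  hdr <- sub("wavelength = \\{[^}]*\\}", "wavelength = {450, 460}", hdr)
  writeLines(hdr, paste0(base, ".hdr"))
  expect_error(read_envi(base), class = "hsim_format_error")
})

test_that("scene directories round trip bitwise", {
  spec <- tiny_spec()
  sc <- generate_patient(spec, "P900", 77)$TN
  dir <- file.path(tempdir(), "scene_rt")
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_identical(back$raw$values, sc$raw$values)
  expect_identical(back$gt_mask, sc$gt_mask)
  expect_identical(back$frames$white, sc$frames$white)
  expect_equal(back$raw$grid$bands, sc$raw$grid$bands)
  expect_equal(back$meta, sc$meta)
  expect_equal(back$raw$resolution_um_per_px, sc$raw$resolution_um_per_px)
})
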