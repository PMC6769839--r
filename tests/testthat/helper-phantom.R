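# Small-scale phantom fixtures used across the suite. Most unit tests run
# on a 9-band 500-580 nm grid (spanning the hemoglobin features, so the
# phantom classes stay separable) to keep scene generation and model fits
# fast; acceptance tests use the full 91-band study conditions.

tiny_grid <- function() build_band_grid(500, 580, 10)

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_size = c(40, 40), grid = tiny_grid(),
                   resolution_um_per_px = 100)
  do.call(scene_spec, utils::modifyList(defaults, args))
}

# deterministic toy cube: values encode (row, col, band) so reshape and IO
# bugs are caught by exact comparison
index_cube <- function(h = 5, w = 4, grid = tiny_grid()) {
  C <- grid$n_bands
  vals <- array(0, c(h, w, C))
  for (b in seq_len(C)) vals[, , b] <- outer(seq_len(h), seq_len(w), function(i, j) i * 100 + j + b / 10)
  hypercube(vals, grid, 25)
}

# brute-force Chebyshev erosion oracle
erode_oracle <- function(mask, n) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rr <- (i - n):(i + n); cc <- (j - n):(j + n)
    inside <- rr >= 1 & rr <= h
    insidec <- cc >= 1 & cc <= w
    out[i, j] <- all(inside) && all(insidec) && all(mask[rr, cc])
  }
  out
}

# O(n^2) Mann-Whitney pair-counting AUC oracle
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive Euclidean distance-to-set oracle
dist_oracle <- function(pts, h, w) {
  out <- matrix(Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  }
  out
}
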