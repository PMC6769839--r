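test_that("the sliding-window lattice enumerates and flushes correctly", {
  # 49x49, size 25, stride 12: offsets {0, 12, 24} per axis -> 9 patches
  expect_equal(hsimargin:::patch_offsets(49L, 25L, 12L), c(0L, 12L, 24L))
  g <- tiny_grid()
  cube49 <- hypercube(array(runif(49 * 49 * 9), c(49, 49, 9)), g)
  gt <- matrix(1L, 49, 49)
  pp <- extract_patches(cube49, patch_spec(25, 13), gt_mask = gt)
  expect_equal(nrow(pp$coords), 9L)
  expect_equal(hsimargin:::patch_spec(25, 13)$stride_px, 12L)
  # 25x25 image: exactly one patch
  cube25 <- hypercube(array(runif(25 * 25 * 9), c(25, 25, 9)), g)
  p1 <- extract_patches(cube25, patch_spec(25, 13), gt_mask = matrix(1L, 25, 25))
  expect_equal(nrow(p1$coords), 1L)
  expect_identical(p1$patches[1, , , ], cube25$values)
  # flush windows appear when stride does not divide the extent
  expect_equal(hsimargin:::patch_offsets(64L, 25L, 12L), c(0L, 12L, 24L, 36L, 39L))
  # too-small images are refused
  cube_small <- hypercube(array(1, c(10, 10, 9)), g)
  expect_error(extract_patches(cube_small, patch_spec(25, 13),
                               gt_mask = matrix(1L, 10, 10)),
               class = "hsim_format_error")
  # lattice coverage: every tissue pixel is covered at least once
  hm <- reconstruct_heatmap(rep(1, nrow(pp$coords)), pp$coords, c(49, 49),
                            patch_spec(25, 13))
  expect_true(all(hm$coverage >= 1))
})

test_that("training-mode patches follow the purity labeling rule", {
  spec <- tiny_spec(image_size = c(40, 40))
  pat <- generate_patient(spec, "P030", 19)
  pn <- extract_patches(pat$N, patch_spec(25, 13), mode = "training")
  expect_true(all(pn$labels == 0L))
  pt <- extract_patches(pat$T, patch_spec(25, 13), mode = "training")
  expect_true(all(pt$labels[pt$purity >= 0.8] == 1L))
  expect_true(all(pt$tissue_frac >= 0.5))
  # inference keeps every tissue-intersecting patch
  pi <- extract_patches(pat$TN, patch_spec(25, 13), mode = "inference")
  expect_gte(nrow(pi$coords), nrow(extract_patches(pat$TN, patch_spec(25, 13),
                                                   mode = "training")$coords))
})

test_that("fold assignment is a balanced patient-level partition", {
  pats <- sprintf("P%02d", 1:10)
  f <- assign_folds(pats, k = 5, seed = 3)
  expect_equal(sort(names(f)), sort(pats))
  expect_true(all(table(f) == 2))
  expect_identical(f, assign_folds(pats, k = 5, seed = 3))
  expect_false(identical(f, assign_folds(pats, k = 5, seed = 4)))
  expect_error(assign_folds(pats[1:3], k = 5), class = "hsim_protocol_error")
  # folds differ by at most one patient and never share a patient, any seed
  for (s in 1:50) {
    pats11 <- sprintf("Q%02d", 1:11)
    f11 <- assign_folds(pats11, k = 5, seed = s)
    tab <- table(f11)
    expect_lte(max(tab) - min(tab), 1)
    expect_equal(sum(tab), 11)
    expect_equal(anyDuplicated(names(f11)), 0L)
  }
})

test_that("heat-map reconstruction equals the brute-force averaging oracle", {
  sp <- patch_spec(4, 2)
  # one patch: constant block
  hm1 <- reconstruct_heatmap(0.7, matrix(c(2, 3), 1), c(8, 8), sp)
  expect_equal(hm1$values[2:5, 3:6], matrix(0.7, 4, 4))
  expect_true(all(is.na(hm1$values[1, ])))
  # two half-overlapping patches: overlap zone is the two-term mean
  hm2 <- reconstruct_heatmap(c(0.2, 0.8), rbind(c(1, 1), c(1, 3)), c(4, 8), sp)
  expect_equal(hm2$values[1:4, 3:4], matrix(0.5, 4, 2))
  expect_equal(hm2$values[1:4, 1:2], matrix(0.2, 4, 2))
  expect_equal(hm2$values[1:4, 5:6], matrix(0.8, 4, 2))
  # random 30-patch toy equals the per-pixel sum/count oracle exactly
  set.seed(61)
  coords <- cbind(sample(1:17, 30, replace = TRUE), sample(1:17, 30, replace = TRUE))
  scores <- runif(30)
  hm <- reconstruct_heatmap(scores, coords, c(20, 20), sp)
  acc <- matrix(0, 20, 20); cnt <- matrix(0, 20, 20)
  for (i in 1:30) {
    rr <- coords[i, 1]:(coords[i, 1] + 3); cc <- coords[i, 2]:(coords[i, 2] + 3)
    for (r in rr) for (c in cc) {
      acc[r, c] <- acc[r, c] + scores[i]; cnt[r, c] <- cnt[r, c] + 1
    }
  }
  expected <- acc / cnt; expected[cnt == 0] <- NA
  expect_identical(hm$values, expected)
  expect_identical(hm$coverage, matrix(as.integer(cnt), 20, 20))
  expect_error(reconstruct_heatmap(0.5, matrix(c(19, 19), 1), c(20, 20), sp),
               class = "hsim_format_error")
})

test_that("the patch classifier learns separable phantoms and respects labels", {
  spec <- tiny_spec(image_size = c(40, 40))
  sp <- patch_spec(15, 7)
  gather <- function(pids, seed0) {
    sets <- lapply(pids, function(i) {
      pat <- generate_patient(spec, sprintf("P%03d", i), seed0 + i)
      list(T = extract_patches(pat$T, sp, mode = "training"),
           N = extract_patches(pat$N, sp, mode = "training"))
    })
    all <- unlist(sets, recursive = FALSE)
    list(patches = do.call(hsimargin:::abind1, lapply(all, `[[`, "patches")),
         labels = unlist(lapply(all, `[[`, "labels")))
  }
  train <- gather(1:3, 100)
  val <- gather(4, 200)
  test <- gather(5, 300)
  cfg <- cnn_config(spectral_channels = 8, block_widths = 6, epochs_max = 15,
                    batch_size = 16, patience = 5, seed = 7)
  model <- train_fold(train, val, cfg, wavelengths = spec$grid$bands)
  expect_gte(model$best_val_auc, 0.9)
  p_test <- predict(model, test$patches)
  expect_true(all(p_test >= 0 & p_test <= 1))
  expect_gte(roc_curve(p_test, test$labels)$auc, 0.9)
  # determinism under the seed
  model2 <- train_fold(train, val, cfg, wavelengths = spec$grid$bands)
  expect_identical(predict(model2, test$patches), p_test)
  # label swap anti-correlates the scores
  train_sw <- train; train_sw$labels <- 1L - train$labels
  val_sw <- val; val_sw$labels <- 1L - val$labels
  model_sw <- train_fold(train_sw, val_sw, cfg, wavelengths = spec$grid$bands)
  p_sw <- predict(model_sw, test$patches)
  expect_lt(stats::cor(p_test, p_sw, method = "spearman"), 0)
  # single-class training is refused
  one_class <- list(patches = train$patches[train$labels == 1L, , , , drop = FALSE],
                    labels = train$labels[train$labels == 1L])
  expect_error(train_fold(one_class, val, cfg), class = "hsim_fit_error")
})

test_that("convolution gradients match finite differences", {
  set.seed(71)
  x <- array(rnorm(2 * 5 * 5 * 3), c(2, 5, 5, 3))
  W <- array(rnorm(3 * 3 * 3 * 4, 0, 0.5), c(3, 3, 3, 4))
  b <- rnorm(4)
  out <- hsimargin:::conv_forward(x, W, b)
  dout <- array(rnorm(length(out)), dim(out))
  bk <- hsimargin:::conv_backward(dout, x, W)
  loss <- function(xx, WW, bb) sum(hsimargin:::conv_forward(xx, WW, bb) * dout)
  eps <- 1e-6
  for (probe in 1:5) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    expect_equal(bk$dx[i], (loss(xp, W, b) - loss(x, W, b)) / eps, tolerance = 1e-4)
    j <- sample(length(W), 1)
    Wp <- W; Wp[j] <- Wp[j] + eps
    expect_equal(bk$dW[j], (loss(x, Wp, b) - loss(x, W, b)) / eps, tolerance = 1e-4)
  }
  expect_equal(bk$db, sapply(1:4, function(k) {
    bp <- b; bp[k] <- bp[k] + eps
    (loss(x, W, bp) - loss(x, W, b)) / eps
  }), tolerance = 1e-4)
})
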