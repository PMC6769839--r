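# Compact inception-style patch classifier, implemented directly on BLAS
# matrix products. Convolutions use same-padding and are computed by
# shift-and-multiply over kernel offsets, which is exact and fast at the
# 25 x 25 patch sizes used here. The network is: 1x1 spectral-mixing
# convolution -> inception blocks (parallel 1x1 / 3x3 / 5x5 branches,
# channel-concatenated) -> global average pooling -> linear logit.
# All ops keep activations in (m, h, w, channels) arrays; because R arrays
# are column-major with m fastest, `matrix(x, m*h*w, f)` is a valid
# zero-copy-order reshape used throughout.

#' Patch-CNN configuration
#'
#' @param spectral_channels output channels of the first (1x1, spectral
#'   mixing) convolution; accepts any input band count.
#' @param block_widths per-branch channel width of each inception block; the
#'   vector length sets the number of blocks.
#' @param kernel_sizes branch kernel sizes within each block.
#' @param epochs_max maximum training epochs (<= 50).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 weight decay.
#' @param patience early-stopping patience on validation AUC (epochs).
#' @param balance undersample the majority class each epoch?
#' @param seed RNG seed controlling initialization, shuffling and balancing.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(spectral_channels = 16, block_widths = c(8, 8),
                       kernel_sizes = c(1, 3, 5), epochs_max = 20,
                       batch_size = 32, learning_rate = 1e-3,
                       weight_decay = 1e-4, patience = 5, balance = TRUE,
                       seed = 1) {
  stopifnot(epochs_max >= 1, epochs_max <= 50, batch_size >= 1,
            all(kernel_sizes %% 2 == 1), length(block_widths) >= 1)
  structure(list(spectral_channels = as.integer(spectral_channels),
                 block_widths = as.integer(block_widths),
                 kernel_sizes = as.integer(kernel_sizes),
                 epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 patience = as.integer(patience), balance = isTRUE(balance),
                 seed = seed),
            class = "cnn_config")
}

conv_init <- function(k, fin, fout) {
  array(stats::rnorm(k * k * fin * fout, 0, sqrt(2 / (k * k * fin))),
        c(k, k, fin, fout))
}

cnn_init_params <- function(C, config) {
  f0 <- config$spectral_channels
  params <- list(stem = list(W = conv_init(1, C, f0), b = numeric(f0)))
  fin <- f0
  params$blocks <- list()
  for (i in seq_along(config$block_widths)) {
    wd <- config$block_widths[i]
    branches <- lapply(config$kernel_sizes, function(k) {
      list(W = conv_init(k, fin, wd), b = numeric(wd))
    })
    names(branches) <- paste0("k", config$kernel_sizes)
    params$blocks[[i]] <- branches
    fin <- wd * length(config$kernel_sizes)
  }
  params$head <- list(W = matrix(stats::rnorm(fin, 0, sqrt(1 / fin)), fin, 1),
                      b = 0)
  params
}

conv_forward <- function(x, W, b) {
  d <- dim(x); m <- d[1]; h <- d[2]; w <- d[3]; fin <- d[4]
  k <- dim(W)[1]; fout <- dim(W)[4]
  if (k == 1L) {
    out <- matrix(x, m * h * w, fin) %*% matrix(W, fin, fout)
  } else {
    p <- (k - 1L) %/% 2L
    xp <- array(0, c(m, h + 2 * p, w + 2 * p, fin))
    xp[, p + seq_len(h), p + seq_len(w), ] <- x
    out <- matrix(0, m * h * w, fout)
    for (dy in seq_len(k)) for (dx in seq_len(k)) {
      xs <- xp[, dy:(dy + h - 1), dx:(dx + w - 1), , drop = FALSE]
      out <- out + matrix(xs, m * h * w, fin) %*% matrix(W[dy, dx, , ], fin, fout)
    }
  }
  out <- out + matrix(b, m * h * w, fout, byrow = TRUE)
  array(out, c(m, h, w, fout))
}

conv_backward <- function(dout, x, W) {
  d <- dim(x); m <- d[1]; h <- d[2]; w <- d[3]; fin <- d[4]
  k <- dim(W)[1]; fout <- dim(W)[4]
  dout_f <- matrix(dout, m * h * w, fout)
  db <- colSums(dout_f)
  dW <- array(0, dim(W))
  if (k == 1L) {
    dW[1, 1, , ] <- crossprod(matrix(x, m * h * w, fin), dout_f)
    dx <- array(dout_f %*% t(matrix(W, fin, fout)), c(m, h, w, fin))
  } else {
    p <- (k - 1L) %/% 2L
    xp <- array(0, c(m, h + 2 * p, w + 2 * p, fin))
    xp[, p + seq_len(h), p + seq_len(w), ] <- x
    dxp <- array(0, dim(xp))
    for (dy in seq_len(k)) for (dx_ in seq_len(k)) {
      xs <- xp[, dy:(dy + h - 1), dx_:(dx_ + w - 1), , drop = FALSE]
      dW[dy, dx_, , ] <- crossprod(matrix(xs, m * h * w, fin), dout_f)
      dxs <- dout_f %*% t(matrix(W[dy, dx_, , ], fin, fout))
      dxp[, dy:(dy + h - 1), dx_:(dx_ + w - 1), ] <-
        dxp[, dy:(dy + h - 1), dx_:(dx_ + w - 1), , drop = FALSE] +
        array(dxs, c(m, h, w, fin))
    }
    dx <- dxp[, p + seq_len(h), p + seq_len(w), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

cnn_forward <- function(x, params, keep_cache = FALSE) {
  cache <- if (keep_cache) list(x = x) else NULL
  pre0 <- conv_forward(x, params$stem$W, params$stem$b)
  a <- pmax(pre0, 0)
  if (keep_cache) { cache$pre0 <- pre0; cache$blocks <- list() }
  for (i in seq_along(params$blocks)) {
    branches <- params$blocks[[i]]
    pres <- lapply(branches, function(br) conv_forward(a, br$W, br$b))
    pre <- do.call(abind4, pres)
    if (keep_cache) cache$blocks[[i]] <- list(input = a, pre = pre)
    a <- pmax(pre, 0)
  }
  d <- dim(a); m <- d[1]; hw <- d[2] * d[3]; f <- d[4]
  gap <- matrix(0, m, f)
  a_flat <- matrix(a, m, hw * f)
  for (j in seq_len(f)) gap[, j] <- rowMeans(a_flat[, ((j - 1) * hw + 1):(j * hw), drop = FALSE])
  z <- as.vector(gap %*% params$head$W + params$head$b)
  if (keep_cache) {
    cache$a_last <- a
    cache$gap <- gap
    cache$z <- z
  }
  list(z = z, cache = cache)
}

# stack 4D patch arrays along the first (patch) dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  ms <- vapply(arrs, function(a) dim(a)[1], integer(1))
  out <- array(0, c(sum(ms), d[2:4]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# concatenate 4D arrays along the channel (4th) dimension
abind4 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  fs <- vapply(arrs, function(a) dim(a)[4], integer(1))
  out <- array(0, c(d[1:3], sum(fs)))
  at <- 0L
  for (a in arrs) {
    f <- dim(a)[4]
    out[, , , at + seq_len(f)] <- a
    at <- at + f
  }
  out
}

# backward pass from dz (m-vector of d(loss)/d(logit)); returns parameter
# gradients plus dx (gradient at the input) and d_a_last (gradient at the
# last block's activations, used by grad-CAM)
cnn_backward <- function(dz, params, cache) {
  grads <- list()
  m <- length(dz)
  gap <- cache$gap
  grads$head <- list(W = crossprod(gap, matrix(dz, m, 1)), b = sum(dz))
  dgap <- matrix(dz, m, 1) %*% t(params$head$W)
  a_last <- cache$a_last
  d <- dim(a_last); h <- d[2]; w <- d[3]; f <- d[4]
  hw <- h * w
  dA <- array(dgap[rep(seq_len(m), hw), ] / hw, c(m, h, w, f))
  d_a_last <- dA
  da <- dA * (a_last > 0)
  grads$blocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    blk <- cache$blocks[[i]]
    branches <- params$blocks[[i]]
    widths <- vapply(branches, function(br) dim(br$W)[4], integer(1))
    at <- 0L
    dinput <- NULL
    gb <- list()
    for (j in seq_along(branches)) {
      dpre_j <- da[, , , at + seq_len(widths[j]), drop = FALSE]
      at <- at + widths[j]
      bk <- conv_backward(dpre_j, blk$input, branches[[j]]$W)
      gb[[names(branches)[j]]] <- list(W = bk$dW, b = bk$db)
      dinput <- if (is.null(dinput)) bk$dx else dinput + bk$dx
    }
    grads$blocks[[i]] <- gb
    da <- dinput * (if (i == 1L) cache$pre0 > 0 else cache$blocks[[i - 1]]$pre > 0)
  }
  bk <- conv_backward(da, cache$x, params$stem$W)
  grads$stem <- list(W = bk$dW, b = bk$db)
  list(grads = grads, dx = bk$dx, d_a_last = d_a_last)
}

# recursive tree walk over matching nested parameter lists; pairs by name
# where names exist (gradient trees are assembled in reverse layer order)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a) else seq_along(a)
    for (nm in keys) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

tree_map0 <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map0(f, a[[nm]])
    out
  } else {
    f(a)
  }
}

adam_step <- function(state, params, grads, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  mh <- tree_map0(function(m) m / (1 - beta1^t), state$m)
  vh <- tree_map0(function(v) v / (1 - beta2^t), state$v)
  upd <- tree_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
  params <- tree_map2(function(p, u) p - lr * u - lr * wd * p, params, upd)
  list(state = state, params = params)
}

normalize_patches <- function(patches, band_mean, band_sd) {
  d <- dim(patches)
  flat <- matrix(patches, prod(d[1:3]), d[4])
  flat <- sweep(sweep(flat, 2, band_mean), 2, band_sd, "/")
  array(flat, d)
}

#' Train the patch CNN for one fold
#'
#' Fits the compact inception-style classifier on labeled 25 x 25 x C
#' training patches, monitoring AUC on a held-out validation patch set for
#' early stopping. Training minimizes binary cross-entropy with Adam; the
#' majority class is undersampled each epoch when `balance` is on. Fully
#' deterministic given `config$seed`.
#'
#' @param train_patches list with `patches` (m x h x w x C array) and
#'   `labels` (0/1), e.g. from [extract_patches()].
#' @param val_patches same structure, from validation patients.
#' @param config a [cnn_config()].
#' @param wavelengths optional band centers (nm) recorded on the model for
#'   saliency profiles.
#' @return an object of class `patch_cnn` with fields `params`, `band_mean`,
#'   `band_sd`, `history`, `best_val_auc`, `config`, `wavelengths`.
#' @export
train_fold <- function(train_patches, val_patches, config = cnn_config(),
                       wavelengths = NULL) {
  x <- train_patches$patches; y <- as.integer(train_patches$labels)
  stopifnot(length(dim(x)) == 4L, length(y) == dim(x)[1])
  if (length(unique(y)) < 2L) {
    hsim_stop("training patches contain a single class", "hsim_fit_error")
  }
  d <- dim(x)
  band_mean <- colMeans(matrix(x, prod(d[1:3]), d[4]))
  band_sd <- pmax(apply(matrix(x, prod(d[1:3]), d[4]), 2, stats::sd), 1e-6)
  x <- normalize_patches(x, band_mean, band_sd)
  xv <- normalize_patches(val_patches$patches, band_mean, band_sd)
  yv <- as.integer(val_patches$labels)
  with_seed(config$seed, {
    params <- cnn_init_params(d[4], config)
    state <- list(m = tree_map0(function(p) p * 0, params),
                  v = tree_map0(function(p) p * 0, params))
    best <- list(auc = -Inf, loss = Inf, params = params, epoch = 0L)
    hist <- list()
    t_step <- 0
    for (epoch in seq_len(config$epochs_max)) {
      idx <- seq_along(y)
      if (config$balance) {
        n_min <- min(table(y))
        idx <- c(sample(which(y == 0L), n_min), sample(which(y == 1L), n_min))
      }
      idx <- sample(idx)
      losses <- c()
      for (start in seq(1, length(idx), by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1, length(idx))]
        xb <- x[bi, , , , drop = FALSE]
        yb <- y[bi]
        fw <- cnn_forward(xb, params, keep_cache = TRUE)
        p <- sigmoid(fw$z)
        losses <- c(losses, -mean(yb * log(pmax(p, 1e-12)) +
                                    (1 - yb) * log(pmax(1 - p, 1e-12))))
        dz <- (p - yb) / length(yb)
        bk <- cnn_backward(dz, params, fw$cache)
        t_step <- t_step + 1
        st <- adam_step(state, params, bk$grads, config$learning_rate,
                        config$weight_decay, t_step)
        state <- st$state; params <- st$params
      }
      val_p <- cnn_predict_raw(params, xv)
      val_auc <- if (length(unique(yv)) > 1L) roc_curve(val_p, yv)$auc else NA_real_
      val_loss <- -mean(yv * log(pmax(val_p, 1e-12)) +
                          (1 - yv) * log(pmax(1 - val_p, 1e-12)))
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_auc = val_auc, val_loss = val_loss)
      # best model by validation AUC; ties (e.g. a saturated AUC of 1)
      # resolved by validation loss so training refines the kept weights
      improved <- !is.na(val_auc) &&
        (val_auc > best$auc + 1e-6 ||
           (val_auc >= best$auc - 1e-6 && val_loss < best$loss - 1e-6))
      if (improved) {
        best <- list(auc = max(val_auc, best$auc), loss = val_loss,
                     params = params, epoch = epoch)
      } else if (!is.na(val_auc) && epoch - best$epoch >= config$patience) {
        break
      }
    }
    structure(list(params = best$params, band_mean = band_mean, band_sd = band_sd,
                   history = do.call(rbind, hist),
                   best_val_auc = best$auc, config = config,
                   wavelengths = wavelengths, input_dims = d[2:4]),
              class = "patch_cnn")
  })
}

cnn_predict_raw <- function(params, x_norm, batch = 256L) {
  m <- dim(x_norm)[1]
  out <- numeric(m)
  for (start in seq(1, m, by = batch)) {
    bi <- start:min(start + batch - 1, m)
    out[bi] <- cnn_forward(x_norm[bi, , , , drop = FALSE], params)$z
  }
  sigmoid(out)
}

#' @export
predict.patch_cnn <- function(object, patches, ...) {
  x <- if (is.list(patches)) patches$patches else patches
  stopifnot(length(dim(x)) == 4L)
  cnn_predict_raw(object$params, normalize_patches(x, object$band_mean, object$band_sd))
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat(sprintf("<patch_cnn> input %s, %d blocks, best val AUC %.3f (epoch %d of %d run)\n",
              paste(x$input_dims, collapse = "x"), length(x$params$blocks),
              x$best_val_auc, nrow(x$history), x$config$epochs_max))
  invisible(x)
}
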