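#' CNN configuration
#'
#' A fixed small convolutional network for mammographic images: four
#' convolution blocks (16, 32, 32 and 64 filters with 28x28, 14x14, 7x7 and
#' 4x4 kernels, stride 1, 'same' padding), each followed by batch
#' normalization, ReLU and 2x2 stride-2 pooling (max pooling in blocks 1-3,
#' average pooling in block 4), then a 100-unit fully-connected layer, a
#' 3-unit output layer and softmax, trained with cross-entropy. Grayscale
#' input is replicated to 3 channels and resized to `input_size`.
#'
#' @param input_size side length the inputs are resized to; must be
#'   divisible by 16 so the four 2x2 poolings are exact (default 32, a
#'   desk-scale setting; 512 reproduces the architecture's nominal input).
#' @param crop_frac central field-of-view fraction cropped before resizing
#'   (default 0.5). Mass classification pipelines conventionally work on a
#'   patch around the lesion rather than the full field; the phantoms place
#'   the mass centrally, so a centered crop plays that role and halves the
#'   downscaling the margins suffer. Set to 1 to disable.
#' @param epochs training epochs (default 10).
#' @param learning_rate SGD step size (default 0.01).
#' @param batch_size minibatch size (default 8).
#' @param momentum SGD momentum (default 0.9).
#' @param augment apply random dihedral (flip/rotate) augmentation to each
#'   training batch (default `TRUE`); standard practice for small training
#'   sets, and label-preserving for mass phenotypes.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return a `cnn_config` list with the architecture tables attached.
#' @export
cnn_config <- function(input_size = 32L, crop_frac = 0.5, epochs = 10L,
                       learning_rate = 0.01, batch_size = 8L,
                       momentum = 0.9, augment = TRUE, seed = 1L) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 16L || input_size %% 16L != 0L)
    stop("`input_size` must be a multiple of 16 (four 2x2 poolings)",
         call. = FALSE)
  if (!is.finite(crop_frac) || crop_frac <= 0 || crop_frac > 1)
    stop("`crop_frac` must be in (0, 1]", call. = FALSE)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(input_size = input_size,
                 crop_frac = crop_frac,
                 channels = 3L,
                 filters = c(16L, 32L, 32L, 64L),
                 kernels = c(28L, 14L, 7L, 4L),
                 pool_types = c("max", "max", "max", "mean"),
                 fc_units = 100L,
                 n_classes = 3L,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer walk of the CNN architecture
#'
#' @param config a [cnn_config].
#' @return a data frame with one row per layer (input, 4 x
#'   conv/batchnorm/ReLU/pool, fully connected, output, softmax,
#'   classification), with filter counts and kernel sizes.
#' @export
cnn_architecture <- function(config = cnn_config()) {
  rows <- list(data.frame(layer = "image_input", filters = NA_integer_,
                          kernel = NA_integer_,
                          detail = sprintf("%d x %d x %d", config$input_size,
                                           config$input_size, config$channels)))
  for (b in seq_len(4L)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "convolution", filters = config$filters[b],
      kernel = config$kernels[b],
      detail = sprintf("%d %dx%d, stride 1, padding 'same'",
                       config$filters[b], config$kernels[b], config$kernels[b]))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "batch_normalization", filters = config$filters[b],
      kernel = NA_integer_, detail = "per-channel")
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "relu", filters = NA_integer_, kernel = NA_integer_,
      detail = "")
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0(config$pool_types[b], "_pooling"),
      filters = NA_integer_, kernel = 2L, detail = "2x2, stride 2")
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "fully_connected", filters = config$fc_units,
    kernel = NA_integer_, detail = "100 units")
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "output", filters = config$n_classes, kernel = NA_integer_,
    detail = "3 logits")
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "softmax", filters = NA_integer_, kernel = NA_integer_,
    detail = "")
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "classification_output", filters = NA_integer_,
    kernel = NA_integer_, detail = "cross-entropy")
  do.call(rbind, rows)
}

# ---- geometry: im2col indices and the col2im scatter matrix ----------------

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- conv_geom_build(H, W, C, k)
  .geom_cache[[key]] <- g
  g
}

conv_geom_build <- function(H, W, C, k) {
  pl <- (k - 1L) %/% 2L                  # left/top 'same' padding
  Hp <- H + k - 1L; Wp <- W + k - 1L
  pos_r <- rep(seq_len(H), times = W)
  pos_c <- rep(seq_len(W), each = H)
  pos_off <- (pos_c - 1L) * Hp + pos_r   # top-left corner of each patch
  eg <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = 0:(C - 1L))
  patch_off <- eg$ch * (Hp * Wp) + eg$dc * Hp + eg$dr
  # HW-major layout: rows = output positions, columns = patch elements
  idx <- outer(pos_off, patch_off, `+`)
  scat <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                               x = 1, dims = c(Hp * Wp * C, length(idx)))
  list(H = H, W = W, C = C, k = k, pl = pl, Hp = Hp, Wp = Wp,
       idx = idx, scat = scat)
}

pad_image <- function(x, geom) {
  # x: (H, W, C) -> zero-padded (Hp, Wp, C)
  out <- array(0, c(geom$Hp, geom$Wp, geom$C))
  out[geom$pl + seq_len(geom$H), geom$pl + seq_len(geom$W), ] <- x
  out
}

# im2col gather, rows = H*W output positions, cols = C*k*k patch elements
im2col <- function(x, geom) {
  cols <- pad_image(x, geom)[geom$idx]
  dim(cols) <- dim(geom$idx)
  cols
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

conv_forward_one <- function(x, tW, b, geom) {
  # returns (H*W) x F activations
  add_bias(im2col(x, geom) %*% tW, b)
}

conv_backward_one <- function(dout_t, x, Wmat, geom, need_dx = TRUE,
                              cols = NULL) {
  # dout_t: (H*W) x F
  if (is.null(cols)) cols <- im2col(x, geom)
  dW <- crossprod(dout_t, cols)          # F x (C*k*k)
  db <- colSums(dout_t)
  if (!need_dx) return(list(dW = dW, db = db, dx = NULL))
  dcols <- dout_t %*% Wmat               # (H*W) x (C*k*k)
  dim(dcols) <- NULL
  dpad <- as.vector(geom$scat %*% dcols)
  dim(dpad) <- c(geom$Hp, geom$Wp, geom$C)
  dx <- dpad[geom$pl + seq_len(geom$H), geom$pl + seq_len(geom$W), ,
             drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# ---- pooling on (H, W, F, B) arrays ---------------------------------------

pool_forward <- function(a, type) {
  H <- dim(a)[1L]
  odd <- seq(1L, H, 2L); even <- odd + 1L
  s <- list(a[odd, odd, , , drop = FALSE], a[even, odd, , , drop = FALSE],
            a[odd, even, , , drop = FALSE], a[even, even, , , drop = FALSE])
  if (type == "max") {
    out <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  } else {
    out <- (s[[1L]] + s[[2L]] + s[[3L]] + s[[4L]]) / 4
  }
  out
}

pool_backward <- function(dout, a, type) {
  H <- dim(a)[1L]
  odd <- seq(1L, H, 2L); even <- odd + 1L
  dx <- array(0, dim(a))
  if (type == "mean") {
    g <- dout / 4
    dx[odd, odd, , ] <- g; dx[even, odd, , ] <- g
    dx[odd, even, , ] <- g; dx[even, even, , ] <- g
    return(dx)
  }
  s <- list(a[odd, odd, , , drop = FALSE], a[even, odd, , , drop = FALSE],
            a[odd, even, , , drop = FALSE], a[even, even, , , drop = FALSE])
  m <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4L)
  for (q in 1:4) {
    masks[[q]] <- (s[[q]] == m) & !taken
    taken <- taken | masks[[q]]
  }
  dx[odd, odd, , ] <- dout * masks[[1L]]
  dx[even, odd, , ] <- dout * masks[[2L]]
  dx[odd, even, , ] <- dout * masks[[3L]]
  dx[even, even, , ] <- dout * masks[[4L]]
  dx
}

# ---- batch normalization over (H, W, F, B): statistics per channel F ------

bn_forward <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a)
  m <- matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  xhat <- sweep(sweep(m, 2L, mu), 2L, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  out <- aperm(array(out, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(out = out, xhat = xhat, mu = mu, v = v, eps = eps)
}

bn_backward <- function(dout, cache, gamma) {
  d <- dim(dout)
  dm <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  inv <- 1 / sqrt(cache$v + cache$eps)
  dxhat_mean <- colMeans(dm)
  dxhat_xhat_mean <- colMeans(dm * xhat)
  dx <- sweep(dm, 2L, dxhat_mean) -
    sweep(xhat, 2L, dxhat_xhat_mean, "*")
  dx <- sweep(dx, 2L, gamma * inv, "*")
  dx <- aperm(array(dx, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_inference <- function(a, gamma, beta, rmu, rv, eps = 1e-5) {
  d <- dim(a)
  m <- matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  xhat <- sweep(sweep(m, 2L, rmu), 2L, sqrt(rv + eps), "/")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  aperm(array(out, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

# ---- parameter initialization ---------------------------------------------

cnn_init <- function(config) {
  p <- list(conv_W = list(), conv_b = list(), gamma = list(), beta = list(),
            run_mu = list(), run_v = list())
  Cin <- config$channels
  for (b in seq_len(4L)) {
    k <- config$kernels[b]; f <- config$filters[b]
    fan_in <- Cin * k * k
    p$conv_W[[b]] <- matrix(stats::rnorm(f * fan_in, 0, sqrt(2 / fan_in)),
                            f, fan_in)
    p$conv_b[[b]] <- rep(0, f)
    p$gamma[[b]] <- rep(1, f)
    p$beta[[b]] <- rep(0, f)
    p$run_mu[[b]] <- rep(0, f)
    p$run_v[[b]] <- rep(1, f)
    Cin <- f
  }
  s_final <- config$input_size %/% 16L
  D <- s_final * s_final * config$filters[4L]
  p$fc_W <- matrix(stats::rnorm(config$fc_units * D, 0, sqrt(2 / D)),
                   config$fc_units, D)
  p$fc_b <- rep(0, config$fc_units)
  p$out_W <- matrix(stats::rnorm(config$n_classes * config$fc_units, 0,
                                 sqrt(2 / config$fc_units)),
                    config$n_classes, config$fc_units)
  p$out_b <- rep(0, config$n_classes)
  p
}

cnn_geoms <- function(config) {
  g <- vector("list", 4L)
  s <- config$input_size
  Cin <- config$channels
  for (b in seq_len(4L)) {
    g[[b]] <- conv_geom(s, s, Cin, config$kernels[b])
    s <- s %/% 2L
    Cin <- config$filters[b]
  }
  # single-channel twin of block 1: grayscale inputs are replicated across
  # the 3 channels, so block 1 can be computed exactly from one channel with
  # the channel-summed kernels (same values, a third of the work)
  attr(g, "g1one") <- conv_geom(config$input_size, config$input_size, 1L,
                                config$kernels[1L])
  g
}

# exact block-1 fast path for channel-replicated input
conv1_replicated_forward <- function(x1, Wmat, b, k, g1, cols = NULL) {
  ksq <- k * k
  Weff <- Wmat[, 1:ksq, drop = FALSE] +
    Wmat[, ksq + (1:ksq), drop = FALSE] +
    Wmat[, 2L * ksq + (1:ksq), drop = FALSE]
  if (is.null(cols)) cols <- im2col(x1, g1)
  add_bias(cols %*% t(Weff), b)
}

conv1_replicated_backward <- function(dout_t, x1, k, g1, cols = NULL) {
  if (is.null(cols)) cols <- im2col(x1, g1)
  dW1 <- crossprod(dout_t, cols)             # F x k^2
  list(dW = cbind(dW1, dW1, dW1), db = colSums(dout_t))
}

# forward through the conv stack for a batch array x (H, W, C, B)
cnn_forward <- function(params, config, geoms, x, training = TRUE) {
  B <- dim(x)[4L]
  caches <- list()
  a <- x
  replicated <- dim(x)[3L] == 3L &&
    identical(x[, , 2L, ], x[, , 1L, ]) && identical(x[, , 3L, ], x[, , 1L, ])
  g1 <- attr(geoms, "g1one")
  for (blk in seq_len(4L)) {
    geom <- geoms[[blk]]
    f <- config$filters[blk]
    tW <- t(params$conv_W[[blk]])
    conv_out <- array(0, c(geom$H, geom$W, f, B))
    cols_cache <- if (training) vector("list", B) else NULL
    for (n in seq_len(B)) {
      if (blk == 1L && replicated) {
        cols <- im2col(a[, , 1L, n], g1)
        out_t <- conv1_replicated_forward(a[, , 1L, n], params$conv_W[[1L]],
                                          params$conv_b[[1L]],
                                          config$kernels[1L], g1, cols)
      } else {
        cols <- im2col(a[, , , n, drop = TRUE], geom)
        out_t <- add_bias(cols %*% tW, params$conv_b[[blk]])
      }
      if (training) cols_cache[[n]] <- cols
      conv_out[, , , n] <- out_t      # (H*W) x F fills (H, W, F) in order
    }
    if (training) {
      bn <- bn_forward(conv_out, params$gamma[[blk]], params$beta[[blk]])
      bn_out <- bn$out
    } else {
      bn <- NULL
      bn_out <- bn_inference(conv_out, params$gamma[[blk]],
                             params$beta[[blk]], params$run_mu[[blk]],
                             params$run_v[[blk]])
    }
    relu_out <- pmax(bn_out, 0)
    pool_out <- pool_forward(relu_out, config$pool_types[blk])
    caches[[blk]] <- list(input = a, conv_out = conv_out, bn = bn,
                          bn_out = bn_out, relu_out = relu_out,
                          cols = cols_cache)
    a <- pool_out
  }
  flat <- matrix(a, ncol = B)                 # D x B, column-major flatten
  fc <- params$fc_W %*% flat + params$fc_b    # 100 x B
  logits <- params$out_W %*% fc + params$out_b
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  ez <- exp(z)
  probs <- sweep(ez, 2L, colSums(ez), "/")
  list(probs = probs, logits = logits, fc = fc, flat = flat,
       caches = caches, final = a, replicated = replicated)
}

cnn_backward <- function(params, config, geoms, fwd, y) {
  # y: 3 x B one-hot; cross-entropy with softmax
  B <- ncol(y)
  grads <- list(conv_W = vector("list", 4L), conv_b = vector("list", 4L),
                gamma = vector("list", 4L), beta = vector("list", 4L))
  dlogits <- (fwd$probs - y) / B
  grads$out_W <- dlogits %*% t(fwd$fc)
  grads$out_b <- rowSums(dlogits)
  dfc <- crossprod(params$out_W, dlogits)
  grads$fc_W <- dfc %*% t(fwd$flat)
  grads$fc_b <- rowSums(dfc)
  dflat <- crossprod(params$fc_W, dfc)
  da <- array(dflat, dim(fwd$final))
  for (blk in 4L:1L) {
    cache <- fwd$caches[[blk]]
    geom <- geoms[[blk]]
    f <- config$filters[blk]
    drelu <- pool_backward(da, cache$relu_out, config$pool_types[blk])
    dbn_out <- drelu * (cache$bn_out > 0)
    bnb <- bn_backward(dbn_out, cache$bn, params$gamma[[blk]])
    grads$gamma[[blk]] <- bnb$dgamma
    grads$beta[[blk]] <- bnb$dbeta
    dconv <- bnb$dx
    dW <- matrix(0, nrow(params$conv_W[[blk]]), ncol(params$conv_W[[blk]]))
    db <- rep(0, f)
    dx <- if (blk > 1L) array(0, dim(cache$input)) else NULL
    for (n in seq_len(dim(dconv)[4L])) {
      dout_n <- dconv[, , , n]
      dim(dout_n) <- c(geom$H * geom$W, f)
      if (blk == 1L && fwd$replicated) {
        cb <- conv1_replicated_backward(dout_n, cache$input[, , 1L, n],
                                        config$kernels[1L],
                                        attr(geoms, "g1one"),
                                        cols = cache$cols[[n]])
      } else {
        cb <- conv_backward_one(dout_n, cache$input[, , , n, drop = TRUE],
                                params$conv_W[[blk]], geom,
                                need_dx = blk > 1L, cols = cache$cols[[n]])
      }
      dW <- dW + cb$dW
      db <- db + cb$db
      if (blk > 1L) dx[, , , n] <- cb$dx
    }
    grads$conv_W[[blk]] <- dW
    grads$conv_b[[blk]] <- db
    da <- dx
  }
  grads
}

# After training, replace the batch-normalization statistics with population
# statistics computed in one pass over the full training set (each block's
# stats are computed from the previous blocks' population-normalized
# outputs), so inference-time normalization matches what the trained weights
# saw much more closely than an exponential running average would.
cnn_population_bn <- function(params, config, geoms, x_all) {
  a <- x_all
  B <- dim(a)[4L]
  replicated <- dim(a)[3L] == 3L &&
    identical(a[, , 2L, ], a[, , 1L, ]) && identical(a[, , 3L, ], a[, , 1L, ])
  for (blk in seq_len(4L)) {
    geom <- geoms[[blk]]
    f <- config$filters[blk]
    tW <- t(params$conv_W[[blk]])
    conv_out <- array(0, c(geom$H, geom$W, f, B))
    for (n in seq_len(B))
      conv_out[, , , n] <- if (blk == 1L && replicated) {
        conv1_replicated_forward(a[, , 1L, n], params$conv_W[[1L]],
                                 params$conv_b[[1L]], config$kernels[1L],
                                 attr(geoms, "g1one"))
      } else {
        conv_forward_one(a[, , , n, drop = TRUE], tW,
                         params$conv_b[[blk]], geom)
      }
    m <- matrix(aperm(conv_out, c(1L, 2L, 4L, 3L)), ncol = f)
    params$run_mu[[blk]] <- colMeans(m)
    params$run_v[[blk]] <- colMeans(m^2) - colMeans(m)^2
    bn_out <- bn_inference(conv_out, params$gamma[[blk]],
                           params$beta[[blk]], params$run_mu[[blk]],
                           params$run_v[[blk]])
    a <- pool_forward(pmax(bn_out, 0), config$pool_types[blk])
  }
  params
}

# dihedral-group transform t in 0..7 of the spatial dims of (H, W, C)
dihedral <- function(x, t) {
  if (t >= 4L) x <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  r <- t %% 4L
  if (r == 0L) return(x)
  for (i in seq_len(r))
    x <- aperm(x[rev(seq_len(dim(x)[1L])), , , drop = FALSE], c(2L, 1L, 3L))
  x
}

# gray images -> (H, W, 3, B) array in roughly [-0.5, 0.5]
cnn_prepare_inputs <- function(images, input_size, crop_frac = 1) {
  B <- length(images)
  x <- array(0, c(input_size, input_size, 3L, B))
  for (n in seq_len(B)) {
    im <- images[[n]]
    if (crop_frac < 1) {
      s <- max(round(min(dim(im)) * crop_frac), input_size %/% 2L)
      s <- min(s, min(dim(im)))
      or <- (nrow(im) - s) %/% 2L
      oc <- (ncol(im) - s) %/% 2L
      im <- gray_image(unclass(im)[or + seq_len(s), oc + seq_len(s)],
                       gray_levels(im))
    }
    im <- resize_gray_image(im, input_size)
    ch <- unclass(im) / (gray_levels(im) - 1) - 0.5
    x[, , 1L, n] <- ch; x[, , 2L, n] <- ch; x[, , 3L, n] <- ch
  }
  x
}

#' Train the image CNN
#'
#' Minibatch SGD with momentum on softmax cross-entropy. Deterministic given
#' `config$seed` (initialization and epoch shuffling both derive from it).
#' After the last epoch, batch-normalization statistics are recomputed as
#' population statistics over the full training set and those are used at
#' prediction time.
#'
#' @param images list of [gray_image]s.
#' @param labels class labels, one per image.
#' @param config a [cnn_config].
#' @return an object of class `cnn_source` with a [predict_proba()] method
#'   and the per-epoch training loss in `$loss_history`.
#' @export
train_cnn <- function(images, labels, config = cnn_config()) {
  labels <- as.character(labels)
  if (length(images) != length(labels))
    stop("`images` and `labels` must align", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set is degenerate: a single class", call. = FALSE)
  y_all <- t(one_hot_encode(labels))          # 3 x N
  x_all <- cnn_prepare_inputs(images, config$input_size, config$crop_frac)
  N <- length(images)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- cnn_init(config)
  geoms <- cnn_geoms(config)
  vel <- rapply(params[c("conv_W", "conv_b", "gamma", "beta",
                         "fc_W", "fc_b", "out_W", "out_b")],
                function(z) z * 0, how = "replace")
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, N, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, N)]
      if (length(take) < 2L) next   # batchnorm needs > 1 sample
      xb <- x_all[, , , take, drop = FALSE]
      if (config$augment) {
        tf <- sample.int(8L, length(take), replace = TRUE) - 1L
        for (q in seq_along(take))
          if (tf[q] > 0L) xb[, , , q] <- dihedral(xb[, , , q, drop = TRUE],
                                                  tf[q])
      }
      yb <- y_all[, take, drop = FALSE]
      fwd <- cnn_forward(params, config, geoms, xb, training = TRUE)
      loss <- -mean(colSums(yb * log(pmax(fwd$probs, 1e-12))))
      grads <- cnn_backward(params, config, geoms, fwd, yb)
      upd <- function(name, blk = NULL) {
        if (is.null(blk)) {
          vel[[name]] <<- config$momentum * vel[[name]] -
            config$learning_rate * grads[[name]]
          params[[name]] <<- params[[name]] + vel[[name]]
        } else {
          vel[[name]][[blk]] <<- config$momentum * vel[[name]][[blk]] -
            config$learning_rate * grads[[name]][[blk]]
          params[[name]][[blk]] <<- params[[name]][[blk]] + vel[[name]][[blk]]
        }
      }
      for (blk in seq_len(4L)) {
        upd("conv_W", blk); upd("conv_b", blk)
        upd("gamma", blk); upd("beta", blk)
      }
      upd("fc_W"); upd("fc_b"); upd("out_W"); upd("out_b")
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
    }
    loss_history[ep] <- ep_loss / max(n_batches, 1L)
  }
  params <- cnn_population_bn(params, config, geoms, x_all)
  structure(list(params = params, config = config,
                 loss_history = loss_history),
            class = c("cnn_source", "probability_source"))
}

#' @export
predict_proba.cnn_source <- function(source, inputs, ...) {
  if (length(inputs) == 0L)
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, mass_classes())))
  config <- source$config
  geoms <- cnn_geoms(config)
  x <- cnn_prepare_inputs(inputs, config$input_size,
                          if (is.null(config$crop_frac)) 1 else config$crop_frac)
  out <- matrix(0, length(inputs), 3L,
                dimnames = list(NULL, mass_classes()))
  bs <- max(config$batch_size, 2L)
  for (start in seq(1L, length(inputs), by = bs)) {
    take <- start:min(start + bs - 1L, length(inputs))
    fwd <- cnn_forward(source$params, config, geoms,
                       x[, , , take, drop = FALSE], training = FALSE)
    out[take, ] <- t(fwd$probs)
  }
  out
}
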