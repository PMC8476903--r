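# Numerical layers for the ranking network: plain-R forward/backward passes
# over single-sample activations. 2D activations are arrays (C, H, W); 1D
# activations are plain numeric vectors. All layers return list(y, cache)
# forward and list(dx, grads) backward.

conv2d_forward <- function(x, w, b, stride) {
  dm <- dim(x); C <- dm[1]; H <- dm[2]; W <- dm[3]
  kd <- dim(w); O <- kd[1]; kh <- kd[3]; kw <- kd[4]
  if (kd[2] != C) stop("conv2d: input has ", C, " channels, kernel expects ", kd[2])
  sh <- stride[1]; sw <- stride[2]
  outH <- floor((H - kh) / sh) + 1
  outW <- floor((W - kw) / sw) + 1
  if (outH < 1 || outW < 1)
    stop("conv2d: non-positive output dimension (input ", H, "x", W,
         ", kernel ", kh, "x", kw, ")")
  n <- outH * outW
  ymat <- matrix(b, O, n)
  rows <- lapply(seq_len(kh), function(ki) seq.int(ki, by = sh, length.out = outH))
  cols <- lapply(seq_len(kw), function(kj) seq.int(kj, by = sw, length.out = outW))
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    xs <- x[, rows[[ki]], cols[[kj]], drop = FALSE]
    dim(xs) <- c(C, n)
    ymat <- ymat + matrix(w[, , ki, kj], O, C) %*% xs
  }
  dim(ymat) <- c(O, outH, outW)
  list(y = ymat,
       cache = list(x = x, w = w, stride = stride, rows = rows, cols = cols,
                    outH = outH, outW = outW))
}

conv2d_backward <- function(dy, cache, need_dx = TRUE) {
  x <- cache$x; w <- cache$w
  dm <- dim(x); C <- dm[1]
  kd <- dim(w); O <- kd[1]; kh <- kd[3]; kw <- kd[4]
  n <- cache$outH * cache$outW
  dymat <- dy; dim(dymat) <- c(O, n)
  db <- rowSums(dymat)
  dw <- array(0, kd)
  dx <- if (need_dx) array(0, dm) else NULL
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    xs <- x[, cache$rows[[ki]], cache$cols[[kj]], drop = FALSE]
    dim(xs) <- c(C, n)
    dw[, , ki, kj] <- dymat %*% t(xs)
    if (need_dx) {
      dxs <- t(matrix(w[, , ki, kj], O, C)) %*% dymat
      dim(dxs) <- c(C, cache$outH, cache$outW)
      dx[, cache$rows[[ki]], cache$cols[[kj]]] <-
        dx[, cache$rows[[ki]], cache$cols[[kj]], drop = FALSE] + dxs
    }
  }
  list(dx = dx, grads = list(w = dw, b = db))
}

maxpool_forward <- function(x) {
  dm <- dim(x); C <- dm[1]; H <- dm[2]; W <- dm[3]
  outH <- H %/% 2L; outW <- W %/% 2L
  if (outH < 1 || outW < 1) stop("maxpool: non-positive output dimension")
  r1 <- seq.int(1, by = 2, length.out = outH)
  c1 <- seq.int(1, by = 2, length.out = outW)
  xs <- list(x[, r1, c1, drop = FALSE], x[, r1 + 1, c1, drop = FALSE],
             x[, r1, c1 + 1, drop = FALSE], x[, r1 + 1, c1 + 1, drop = FALSE])
  y <- pmax(pmax(xs[[1]], xs[[2]]), pmax(xs[[3]], xs[[4]]))
  # route gradient to the first (in scan order) voxel attaining the max
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4)
  for (k in 1:4) {
    m <- (xs[[k]] == y) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(y = y, cache = list(dim = dm, r1 = r1, c1 = c1, masks = masks))
}

maxpool_backward <- function(dy, cache) {
  dx <- array(0, cache$dim)
  r1 <- cache$r1; c1 <- cache$c1
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4)
    dx[, r1 + off[[k]][1], c1 + off[[k]][2]] <- dy * cache$masks[[k]]
  list(dx = dx, grads = NULL)
}

leaky_relu_forward <- function(x, slope = 0.01) {
  neg <- !is.na(x) & x < 0  # non-finite activations pass through to the
                            # loss guard instead of failing here
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, cache = list(neg = neg, slope = slope))
}

leaky_relu_backward <- function(dy, cache) {
  dx <- dy
  dx[cache$neg] <- cache$slope * dy[cache$neg]
  list(dx = dx, grads = NULL)
}

linear_forward <- function(x, w, b) {
  list(y = as.numeric(w %*% x + b), cache = list(x = x, w = w))
}

linear_backward <- function(dy, cache) {
  list(dx = as.numeric(crossprod(cache$w, dy)),
       grads = list(w = outer(dy, cache$x), b = dy))
}

# Batch normalization over per-feature groups. `x` arrives as a (F, n)
# matrix: F channels with n spatial elements each (2D case, n = H*W) or
# F features with n = 1 (1D case, single-sample batch). With n > 1 the
# current group's statistics are used in training AND inference (with
# single-sample batches this is instance normalization; using running
# averages at inference would make the output depend on unrelated samples
# and diverge from the training-time behaviour); the running moments are
# updated in training only. With n == 1 group statistics are degenerate,
# so normalization falls back to the running moments (whose mean tracks
# the samples during training).
batchnorm_forward <- function(xmat, p, s, training, momentum = 0.1,
                              eps = 1e-5) {
  n <- ncol(xmat)
  if (n > 1) {
    mu <- rowMeans(xmat)
    xc <- xmat - mu
    var_b <- rowMeans(xc^2)
    istd <- 1 / sqrt(var_b + eps)
    xhat <- xc * istd
    if (training) {
      s$mean <- (1 - momentum) * s$mean + momentum * mu
      s$var <- (1 - momentum) * s$var + momentum * var_b * n / max(n - 1, 1)
    }
    mode <- "batch"
  } else {
    istd <- 1 / sqrt(s$var + eps)
    xhat <- (xmat - s$mean) * istd
    if (training) # n == 1: track the mean, normalize by pre-update moments
      s$mean <- (1 - momentum) * s$mean + momentum * as.numeric(xmat)
    mode <- "running"
  }
  y <- xhat * p$gamma + p$beta
  list(y = y, state = s,
       cache = list(xhat = xhat, istd = istd, gamma = p$gamma, mode = mode))
}

batchnorm_backward <- function(dy, cache) {
  xhat <- cache$xhat
  n <- ncol(dy)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  if (cache$mode == "batch") {
    dx <- (cache$istd / n) *
      (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dx <- dxhat * cache$istd
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}
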