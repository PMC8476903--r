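#' Network architecture specification
#'
#' Builds the layer-by-layer specification of the beam-angle ranking network:
#' a convolutional feature extractor followed by a fully connected predictor.
#' The first convolution (kernel 9x1, stride 9) merges the nine per-bin
#' features of one ray into a weighted geometric feature; the second (kernel
#' 25x1, stride 25) merges the 25 rays of one gantry angle into a single
#' weighted ray; the remaining convolutions are 3x3 stride-1 with
#' max-pooling. Every convolution and every fully connected layer except the
#' last is followed by batch normalization and a leaky rectified linear
#' activation. With the defaults the specification reproduces the published
#' architecture exactly: input (1, 40500, 4000), eight convolution layers,
#' four fully connected layers 1220 -> 560 -> 560 -> 560 -> 360.
#'
#' The fully connected input size is derived by shape inference from the
#' convolution stack, so reduced-resolution variants (fewer angles, bins,
#' 3x3 stages or hidden units) stay internally consistent.
#'
#' @param n_angles number of sampled gantry angles (default 180, i.e. 2 deg
#'   steps).
#' @param n_rays rays per angle (default 25).
#' @param n_features features per ray (default 9: HU + 8 structures).
#' @param n_bins bins per ray (default 4000).
#' @param conv_channels output channels of the 3x3 convolution stages
#'   (default `c(3, 9, 27, 9, 3, 1)`).
#' @param pool_after logical per 3x3 stage: follow with 2x2 max-pool
#'   (default pools after the first four stages).
#' @param hidden sizes of the hidden fully connected layers
#'   (default `c(560, 560, 560)`).
#' @param n_out output length (default 360, one score per degree).
#' @param leaky_slope negative slope of the leaky rectified linear
#'   activation (default 0.01).
#' @return object of class `baods_netspec`: list with `layers`,
#'   `input_shape` (C, H, W), `n_out`, `leaky_slope`.
#' @export
baods_netspec <- function(n_angles = 180, n_rays = 25, n_features = 9,
                          n_bins = 4000,
                          conv_channels = c(3, 9, 27, 9, 3, 1),
                          pool_after = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                          hidden = c(560, 560, 560), n_out = 360,
                          leaky_slope = 0.01) {
  if (length(pool_after) != length(conv_channels))
    stop("pool_after must match conv_channels in length")
  H0 <- n_angles * n_rays * n_features
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  add(list(type = "conv", out = 1L, in_ch = 1L, kh = n_features, kw = 1L,
           sh = n_features, sw = 1L, label = "conv1 (feature merge)"))
  add(list(type = "bn2d", features = 1L))
  add(list(type = "act"))
  add(list(type = "conv", out = 1L, in_ch = 1L, kh = n_rays, kw = 1L,
           sh = n_rays, sw = 1L, label = "conv2 (ray merge)"))
  add(list(type = "bn2d", features = 1L))
  add(list(type = "act"))
  prev <- 1L
  for (i in seq_along(conv_channels)) {
    ch <- as.integer(conv_channels[i])
    add(list(type = "conv", out = ch, in_ch = prev, kh = 3L, kw = 3L,
             sh = 1L, sw = 1L, label = sprintf("conv%d (3x3)", i + 2L)))
    add(list(type = "bn2d", features = ch))
    add(list(type = "act"))
    if (pool_after[i]) add(list(type = "pool"))
    prev <- ch
  }
  add(list(type = "flatten"))
  spec <- structure(
    list(layers = layers, input_shape = c(1L, H0, as.integer(n_bins)),
         n_out = as.integer(n_out), leaky_slope = leaky_slope),
    class = "baods_netspec")
  flat <- utils::tail(shape_inference(spec), 1)[[1]]$shape
  prev <- as.integer(flat)
  for (h in hidden) {
    add(list(type = "linear", out = as.integer(h), in_size = prev))
    add(list(type = "bn1d", features = as.integer(h)))
    add(list(type = "act"))
    prev <- as.integer(h)
  }
  add(list(type = "linear", out = as.integer(n_out), in_size = prev))
  spec$layers <- layers
  # validate the full stack
  shape_inference(spec)
  spec
}

#' @export
print.baods_netspec <- function(x, ...) {
  sh <- shape_inference(x)
  cat(sprintf("<baods_netspec> input (C,H,W) = (%s), output %d\n",
              paste(x$input_shape, collapse = ", "), x$n_out))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %2d %-8s -> (%s)\n", i, l$type,
                paste(sh[[i]]$shape, collapse = ", ")))
  }
  invisible(x)
}

#' Per-layer output shapes without running the network
#'
#' Computes the shape after every layer by arithmetic alone: a convolution
#' maps H to `floor((H - kh)/sh) + 1` (no padding; the stride-matched 9x1 and
#' 25x1 kernels tile exactly, so their "same" padding is zero), max-pooling
#' halves both spatial dimensions with floor, flatten multiplies out.
#'
#' @param spec a [baods_netspec()].
#' @param input_shape length-3 (C, H, W); defaults to the spec's input shape.
#' @return list with one entry per layer: `list(type, shape)` where `shape`
#'   is `c(C, H, W)` for 2D layers or a single length for flatten/linear
#'   layers.
#' @export
shape_inference <- function(spec, input_shape = spec$input_shape) {
  sh <- as.integer(input_shape)
  out <- vector("list", length(spec$layers))
  flat <- NULL
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      if (sh[1] != l$in_ch)
        stop("layer ", i, " (", l$label, "): expects ", l$in_ch,
             " channels, got ", sh[1])
      sh <- c(l$out,
              (sh[2] - l$kh) %/% l$sh + 1L,
              (sh[3] - l$kw) %/% l$sw + 1L)
      if (any(sh[2:3] < 1))
        stop("layer ", i, " (", l$label, "): non-positive output dimension")
    } else if (l$type == "pool") {
      sh <- c(sh[1], sh[2] %/% 2L, sh[3] %/% 2L)
      if (any(sh[2:3] < 1))
        stop("layer ", i, " (pool): non-positive output dimension")
    } else if (l$type == "flatten") {
      flat <- prod(sh)
    } else if (l$type == "linear") {
      if (flat != l$in_size)
        stop("layer ", i, " (linear): expects input ", l$in_size,
             ", got ", flat)
      flat <- l$out
    } else if (l$type == "bn1d") {
      # no shape change
    }
    out[[i]] <- list(type = l$type,
                     shape = if (is.null(flat)) sh else flat)
  }
  out
}

#' Instantiate a network from its specification
#'
#' Allocates and randomly initializes all parameters (He-scaled weights;
#' uniformly drawn biases on every convolution and fully connected layer;
#' batch-normalization scale 1, offset 0, running moments 0/1). With a fixed
#' seed the initialization is fully deterministic.
#'
#' @param spec a [baods_netspec()].
#' @param seed integer RNG seed for the initialization.
#' @return object of class `baods_net` with fields `spec`, `params`,
#'   `state`, `trace` (NULL until trained).
#' @export
build_net <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "baods_netspec"))
  set.seed(seed)
  params <- vector("list", length(spec$layers))
  state <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$in_ch * l$kh * l$kw
      bound <- 1 / sqrt(fan_in)
      params[[i]] <- list(
        w = array(stats::rnorm(l$out * l$in_ch * l$kh * l$kw,
                               sd = sqrt(2 / fan_in)),
                  dim = c(l$out, l$in_ch, l$kh, l$kw)),
        b = stats::runif(l$out, -bound, bound))
    } else if (l$type == "linear") {
      bound <- 1 / sqrt(l$in_size)
      params[[i]] <- list(
        w = matrix(stats::rnorm(l$out * l$in_size, sd = sqrt(2 / l$in_size)),
                   l$out, l$in_size),
        b = stats::runif(l$out, -bound, bound))
    } else if (l$type %in% c("bn2d", "bn1d")) {
      params[[i]] <- list(gamma = rep(1, l$features),
                          beta = rep(0, l$features))
      state[[i]] <- list(mean = rep(0, l$features),
                         var = rep(1, l$features))
    }
  }
  structure(list(spec = spec, params = params, state = state, trace = NULL,
                 seed = seed),
            class = "baods_net")
}

#' Run the network forward on one sample
#'
#' @param net a `baods_net`.
#' @param x input: a (C, H, W) array or an (H, W) matrix (C = 1 implied).
#' @param training use training-mode batch normalization (updates running
#'   statistics) and keep layer caches for backpropagation.
#' @param keep_cache keep per-layer caches (defaults to `training`).
#' @return list with `y` (the raw output vector), `caches`, `shapes` (the
#'   realized per-layer output shapes) and `net` (with updated
#'   normalization state when training).
#' @export
net_forward <- function(net, x, training = FALSE, keep_cache = training) {
  spec <- net$spec
  if (is.matrix(x)) dim(x) <- c(1L, nrow(x), ncol(x))
  if (!identical(as.integer(dim(x)), as.integer(spec$input_shape)))
    stop("input shape (", paste(dim(x), collapse = ", "),
         ") does not match spec input (",
         paste(spec$input_shape, collapse = ", "), ")")
  caches <- vector("list", length(spec$layers))
  shapes <- vector("list", length(spec$layers))
  cur <- x
  cur2d <- TRUE
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      r <- conv2d_forward(cur, net$params[[i]]$w, net$params[[i]]$b,
                          c(l$sh, l$sw))
      cur <- r$y; if (keep_cache) caches[[i]] <- r$cache
    } else if (l$type == "pool") {
      r <- maxpool_forward(cur)
      cur <- r$y; if (keep_cache) caches[[i]] <- r$cache
    } else if (l$type == "act") {
      r <- leaky_relu_forward(cur, spec$leaky_slope)
      cur <- r$y; if (keep_cache) caches[[i]] <- r$cache
    } else if (l$type == "bn2d") {
      dm <- dim(cur)
      xm <- cur; dim(xm) <- c(dm[1], dm[2] * dm[3])
      r <- batchnorm_forward(xm, net$params[[i]], net$state[[i]], training)
      net$state[[i]] <- r$state
      cur <- r$y; dim(cur) <- dm
      if (keep_cache) caches[[i]] <- r$cache
    } else if (l$type == "bn1d") {
      xm <- matrix(cur, length(cur), 1)
      r <- batchnorm_forward(xm, net$params[[i]], net$state[[i]], training)
      net$state[[i]] <- r$state
      cur <- as.numeric(r$y)
      if (keep_cache) caches[[i]] <- r$cache
    } else if (l$type == "flatten") {
      if (keep_cache) caches[[i]] <- list(dim = dim(cur))
      cur <- as.numeric(cur)
      cur2d <- FALSE
    } else if (l$type == "linear") {
      r <- linear_forward(cur, net$params[[i]]$w, net$params[[i]]$b)
      cur <- r$y; if (keep_cache) caches[[i]] <- r$cache
    }
    shapes[[i]] <- if (cur2d) dim(cur) else length(cur)
  }
  list(y = cur, caches = caches, shapes = shapes, net = net)
}

# backward pass: dy is dLoss/dy at the output. Returns per-layer grads
# (NULL for parameter-free layers).
net_backward <- function(net, caches, dy) {
  spec <- net$spec
  grads <- vector("list", length(spec$layers))
  cur <- dy
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      # the first layer's input gradient is never consumed
      r <- conv2d_backward(cur, caches[[i]], need_dx = i > 1L)
    } else if (l$type == "pool") {
      r <- maxpool_backward(cur, caches[[i]])
    } else if (l$type == "act") {
      r <- leaky_relu_backward(cur, caches[[i]])
    } else if (l$type == "bn2d") {
      dm <- dim(cur)
      dym <- cur; dim(dym) <- c(dm[1], dm[2] * dm[3])
      r <- batchnorm_backward(dym, caches[[i]])
      dim(r$dx) <- dm
    } else if (l$type == "bn1d") {
      r <- batchnorm_backward(matrix(cur, length(cur), 1), caches[[i]])
      r$dx <- as.numeric(r$dx)
    } else if (l$type == "flatten") {
      r <- list(dx = array(cur, caches[[i]]$dim), grads = NULL)
    } else if (l$type == "linear") {
      r <- linear_backward(cur, caches[[i]])
    }
    grads[i] <- list(r$grads)
    cur <- r$dx
  }
  grads
}

#' Total number of trainable parameters
#'
#' @param x a `baods_net` or `baods_netspec`.
#' @return integer parameter count (convolutions: out*in*kh*kw + out;
#'   linears: out*in + out; batch normalizations: 2*features).
#' @export
n_params <- function(x) {
  spec <- if (inherits(x, "baods_net")) x$spec else x
  tot <- 0
  for (l in spec$layers) {
    tot <- tot + switch(l$type,
      conv = l$out * l$in_ch * l$kh * l$kw + l$out,
      linear = l$out * l$in_size + l$out,
      bn2d = 2 * l$features,
      bn1d = 2 * l$features,
      0)
  }
  as.integer(tot)
}

#' Training losses: L1, L2 and smooth-L1
#'
#' Mean over all elements of the per-element term: `|x - y|` (L1),
#' `(x - y)^2` (L2), or the smooth-L1 term `0.5 (x - y)^2 / beta` when
#' `|x - y| < beta` and `|x - y| - 0.5 beta` otherwise. The two smooth-L1
#' branches meet continuously at `|x - y| = beta`.
#'
#' @param x reference ranking scores.
#' @param y predicted ranking scores (same length).
#' @param type one of `"smooth_l1"`, `"l1"`, `"l2"`.
#' @param beta smooth-L1 threshold (> 0, default 0.5).
#' @return scalar loss.
#' @export
baods_loss <- function(x, y, type = c("smooth_l1", "l1", "l2"), beta = 0.5) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (beta <= 0) stop("beta must be > 0")
  d <- abs(x - y)
  z <- switch(type,
    l1 = d,
    l2 = d^2,
    smooth_l1 = ifelse(d < beta, 0.5 * d^2 / beta, d - 0.5 * beta))
  mean(z)
}

# dLoss/dy (y = prediction)
baods_loss_grad <- function(x, y, type, beta = 0.5) {
  n <- length(x)
  d <- y - x
  switch(type,
    l1 = sign(d) / n,
    l2 = 2 * d / n,
    smooth_l1 = ifelse(abs(d) < beta, d / beta, sign(d)) / n)
}

#' Predict the beam-angle ranking score for one feature tensor
#'
#' Runs the network in evaluation mode (batch-normalization running
#' statistics) and clamps the output into \[0, 1\] for downstream selection;
#' clamping does not change the ranking of in-range scores.
#'
#' @param net a `baods_net` (typically from [baods_fit()]).
#' @param features a feature tensor matrix (rows x bins) as produced by
#'   [build_feature_tensor()], or a (1, H, W) array.
#' @return numeric vector of length `spec$n_out` (default 360) in \[0, 1\].
#' @export
predict_sbeam <- function(net, features) {
  if (inherits(features, "baods_features")) features <- features$values
  y <- net_forward(net, features, training = FALSE, keep_cache = FALSE)$y
  pmin(pmax(y, 0), 1)
}
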