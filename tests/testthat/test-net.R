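table1_shapes <- function() {
  # printed architecture: (C, H, W) after each conv/pool stage of the
  # full-size network, plus the flattened size and linear widths
  list(conv = list(c(1, 4500, 4000), c(1, 180, 4000), c(3, 178, 3998),
                   c(9, 87, 1997), c(27, 41, 996), c(9, 18, 496),
                   c(3, 7, 246), c(1, 5, 244)),
       pool = list(c(3, 89, 1999), c(9, 43, 998), c(27, 20, 498),
                   c(9, 9, 248)),
       flatten = 1220,
       linear = c(560, 560, 560, 360))
}

test_that("shape inference reproduces every printed layer shape", {
  spec <- baods_netspec()
  sh <- shape_inference(spec)
  types <- vapply(spec$layers, function(l) l$type, character(1))
  ref <- table1_shapes()
  conv_sh <- lapply(sh[types == "conv"], `[[`, "shape")
  pool_sh <- lapply(sh[types == "pool"], `[[`, "shape")
  lin_sh <- vapply(sh[types == "linear"], `[[`, numeric(1), "shape")
  expect_equal(lapply(conv_sh, as.numeric), ref$conv)
  expect_equal(lapply(pool_sh, as.numeric), ref$pool)
  expect_equal(sh[[which(types == "flatten")]]$shape, ref$flatten)
  expect_equal(as.numeric(lin_sh), ref$linear)
  expect_equal(sum(types == "conv"), 8L)
  expect_equal(sum(types == "linear"), 4L)
})

test_that("shape inference rejects inconsistent specs with the layer named", {
  spec <- baods_netspec(n_angles = 8, n_bins = 40, conv_channels = c(3, 1),
                        pool_after = c(FALSE, FALSE), hidden = 16)
  expect_error(shape_inference(spec, c(1, 10, 40)), "conv")
  expect_error(baods_netspec(n_angles = 1, n_bins = 10,
                             conv_channels = c(3, 9, 27),
                             pool_after = c(TRUE, TRUE, TRUE), hidden = 16),
               "non-positive")
})

test_that("parameter count matches the closed-form per-layer formulas", {
  spec <- baods_netspec()
  # independent count: conv out*in*kh*kw + out; bn 2f; linear out*in + out
  expected <- (1 * 1 * 9 * 1 + 1) + 2 +
    (1 * 1 * 25 * 1 + 1) + 2 +
    (3 * 1 * 3 * 3 + 3) + 6 +
    (9 * 3 * 3 * 3 + 9) + 18 +
    (27 * 9 * 3 * 3 + 27) + 54 +
    (9 * 27 * 3 * 3 + 9) + 18 +
    (3 * 9 * 3 * 3 + 3) + 6 +
    (1 * 3 * 3 * 3 + 1) + 2 +
    (560 * 1220 + 560) + 1120 +
    (560 * 560 + 560) + 1120 +
    (560 * 560 + 560) + 1120 +
    (360 * 560 + 360)
  expect_equal(n_params(spec), expected)
})

test_that("initialization is deterministic under a fixed seed", {
  spec <- reduced_spec(n_angles = 8, n_bins = 40)
  a <- build_net(spec, seed = 42)
  b <- build_net(spec, seed = 42)
  expect_identical(a$params, b$params)
  c <- build_net(spec, seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("forward pass on zeros is finite with the right output length", {
  spec <- reduced_spec(n_angles = 8, n_bins = 40)
  net <- build_net(spec, seed = 1)
  x <- matrix(0, spec$input_shape[2], spec$input_shape[3])
  y <- net_forward(net, x)$y
  expect_length(y, 360)
  expect_true(all(is.finite(y)))
  expect_error(net_forward(net, matrix(0, 10, 10)), "shape")
})

test_that("shape inference agrees with an actual forward pass layer by layer", {
  for (spec in list(reduced_spec(n_angles = 8, n_bins = 40),
                    baods_netspec(n_angles = 12, n_bins = 120,
                                  conv_channels = c(3, 9, 3),
                                  pool_after = c(TRUE, FALSE, FALSE),
                                  hidden = c(32, 32)))) {
    net <- build_net(spec, seed = 2)
    x <- array(stats::rnorm(prod(spec$input_shape)), spec$input_shape)
    fw <- net_forward(net, x)
    si <- shape_inference(spec)
    for (i in seq_along(si))
      expect_equal(as.integer(fw$shapes[[i]]), as.integer(si[[i]]$shape))
  }
})

test_that("losses are zero iff equal and match hand-evaluated branch values", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(baods_loss(x, x, "l1"), 0)
  expect_equal(baods_loss(x, x, "l2"), 0)
  expect_equal(baods_loss(x, x, "smooth_l1"), 0)
  # single elements, beta = 0.5: quadratic branch 0.5 d^2 / beta
  expect_equal(baods_loss(0, 0.25, "smooth_l1"), 0.0625)
  # linear branch d - beta/2
  expect_equal(baods_loss(0, 0.75, "smooth_l1"), 0.5)
  # continuity at |d| = beta: both branches give 0.25
  expect_equal(baods_loss(0, 0.5, "smooth_l1"), 0.25)
  expect_equal(0.5 * 0.5^2 / 0.5, 0.5 - 0.5 * 0.5)
  expect_equal(baods_loss(c(1, 0), c(0, 0), "l1"), 0.5)
  expect_equal(baods_loss(c(1, 0), c(0, 0), "l2"), 0.5)
  expect_error(baods_loss(1:3, 1:2, "l1"), "length")
  expect_true(baods_loss(runif(10), runif(10), "smooth_l1") >= 0)
})

test_that("smooth-L1 equals its piecewise closed form elementwise", {
  set.seed(7)
  d <- runif(200, -2, 2)
  z <- vapply(d, function(di)
    baods_loss(0, di, "smooth_l1", beta = 0.5), numeric(1))
  ref <- ifelse(abs(d) < 0.5, 0.5 * d^2 / 0.5, abs(d) - 0.25)
  expect_equal(z, ref)
})

test_that("analytic gradients match finite differences away from kinks", {
  spec <- baods_netspec(n_angles = 4, n_rays = 2, n_features = 3,
                        n_bins = 24, conv_channels = c(2),
                        pool_after = c(FALSE), hidden = c(8), n_out = 6)
  net <- build_net(spec, seed = 7)
  set.seed(42)
  x <- array(stats::rnorm(prod(spec$input_shape)), spec$input_shape)
  yref <- stats::runif(6)
  lossfun <- function(net) {
    fw <- net_forward(net, x, training = TRUE)
    baods_loss(yref, fw$y, "l2")
  }
  fw <- net_forward(net, x, training = TRUE)
  dy <- baods:::baods_loss_grad(yref, fw$y, "l2")
  grads <- net_backward(fw$net, fw$caches, dy)
  eps <- 1e-4
  for (li in seq_along(net$params)) {
    if (is.null(grads[[li]])) next
    for (f in names(grads[[li]])) {
      p <- net$params[[li]][[f]]
      idx <- sample(length(p), min(4, length(p)))
      for (i in idx) {
        np <- net
        np$params[[li]][[f]][i] <- p[i] + eps
        lp <- lossfun(np)
        np$params[[li]][[f]][i] <- p[i] - eps
        lm <- lossfun(np)
        num <- (lp - lm) / (2 * eps)
        expect_equal(grads[[li]][[f]][i], num, tolerance = 5e-3)
      }
    }
  }
})

test_that("prediction clamps to the unit interval without changing ranks", {
  spec <- reduced_spec(n_angles = 8, n_bins = 40)
  net <- build_net(spec, seed = 3)
  x <- matrix(stats::rnorm(spec$input_shape[2] * spec$input_shape[3]),
              spec$input_shape[2], spec$input_shape[3])
  p <- predict_sbeam(net, x)
  expect_length(p, 360)
  expect_true(all(p >= 0 & p <= 1))
  # clamping leaves in-range values untouched and preserves their ranking
  set.seed(5)
  for (i in 1:20) {
    v <- stats::runif(360)
    cl <- pmin(pmax(v, 0), 1)
    expect_identical(cl, v)
    expect_identical(order(cl), order(v))
  }
})
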