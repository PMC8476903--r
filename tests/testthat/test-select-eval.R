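test_that("selection recovers well-separated clinical angles exactly", {
  s <- make_sbeam(c(140, 190, 240))
  expect_equal(sort(select_angles(s)), c(140, 190, 240))
})

test_that("the 30-degree rule skips close runners-up", {
  s <- numeric(360)
  s[c(0, 10, 90, 200) + 1] <- c(1.0, 0.9, 0.8, 0.7)
  expect_equal(select_angles(s), c(0, 90, 200))
  # circular wrap: 350 is only 10 deg from 0
  s2 <- numeric(360)
  s2[c(0, 350, 180) + 1] <- c(1.0, 0.9, 0.8)
  expect_equal(select_angles(s2, k = 2), c(0, 180))
})

test_that("selection matches a step-by-step greedy oracle on random scores", {
  greedy_oracle <- function(s, k, min_sep) {
    ang <- 0:359
    remaining <- order(-s, ang) # ties: lower angle first
    acc <- c()
    for (i in remaining) {
      a <- ang[i]
      ok <- TRUE
      for (b in acc) {
        d <- abs(a - b) %% 360
        if (min(d, 360 - d) < min_sep) { ok <- FALSE; break }
      }
      if (ok) acc <- c(acc, a)
      if (length(acc) == k) break
    }
    acc
  }
  set.seed(17)
  for (i in 1:1000) {
    s <- stats::runif(360)
    expect_equal(select_angles(s), as.numeric(greedy_oracle(s, 3, 30)))
  }
  # with ties
  for (i in 1:50) {
    s <- sample(seq(0, 1, by = 0.25), 360, replace = TRUE)
    expect_equal(select_angles(s), as.numeric(greedy_oracle(s, 3, 30)))
  }
})

test_that("selected angles always satisfy the beam-set invariant", {
  set.seed(23)
  for (i in 1:200) {
    s <- stats::runif(360)
    sel <- select_angles(s)
    expect_length(sel, 3)
    expect_true(all(sel >= 0 & sel < 360))
    seps <- combn(sel, 2, function(p) circ_dist(p[1], p[2]))
    expect_true(all(seps >= 30))
    expect_true(all(diff(s[sel + 1]) <= 0))  # non-increasing score order
  }
  expect_error(select_angles(rep(1, 360), k = 13, min_sep = 30),
               "12 angle")
})

test_that("conformity index is 1 for a perfect plan and matches hand counts", {
  g <- volume_grid(array(0, c(10, 10, 5)), c(1, 1, 1))
  tv <- array(0L, dim(g$voxels)); tv[3:6, 3:6, 2:4] <- 1L
  d <- array(0, dim(g$voxels)); d[tv == 1L] <- 100
  dg <- dose_grid(d, g)
  expect_equal(conformity_index(tv, dg), 1)
  expect_equal(conformity_index(tv, dg, "paddick"), 1)
  # TV = 100, PIV = 200, overlap = 100 -> ratio 2.0, Paddick 0.5
  g2 <- volume_grid(array(0, c(20, 20, 1)), c(1, 1, 1))
  tv2 <- array(0L, dim(g2$voxels)); tv2[1:10, 1:10, 1] <- 1L
  d2 <- array(0, dim(g2$voxels)); d2[1:20, 1:10, 1] <- 100
  dg2 <- dose_grid(d2, g2)
  expect_equal(conformity_index(tv2, dg2), 2.0)
  expect_equal(conformity_index(tv2, dg2, "paddick"), 0.5)
  expect_equal(conformity_index(tv2, dg2),
               1 / conformity_index(tv2, dg2, "paddick"))
  # empty overlap is undefined
  d3 <- array(0, dim(g2$voxels)); d3[15:20, 15:20, 1] <- 100
  expect_warning(ci <- conformity_index(tv2, dose_grid(d3, g2)), "overlap")
  expect_true(is.nan(ci))
  expect_error(conformity_index(array(0L, dim(g2$voxels)), dg2), "empty")
})

test_that("shrinking the isodose volume toward the target drives the index to 1", {
  # nested spheres: PIV radius sweeps down toward the TV radius
  n <- 24
  g <- volume_grid(array(0, c(n, n, n)), c(1, 1, 1))
  ax <- baods:::grid_axes(g)
  cen <- c(n / 2, n / 2, n / 2)
  rad <- function(r) {
    a <- array(0L, c(n, n, n))
    for (k in 1:n) {
      dz2 <- (ax[[3]][k] - cen[3])^2
      a[, , k] <- as.integer(outer((ax[[1]] - cen[1])^2,
                                   (ax[[2]] - cen[2])^2, "+") + dz2 <= r^2)
    }
    a
  }
  tv <- rad(5)
  cis <- sapply(c(10, 8, 6.5, 5), function(r) {
    d <- array(0, c(n, n, n)); d[rad(r) == 1L] <- 100
    conformity_index(tv, dose_grid(d, g))
  })
  expect_true(all(diff(cis) < 0))
  expect_equal(cis[4], 1)
})

test_that("V_x is the masked fraction at or above the threshold", {
  g <- volume_grid(array(0, c(10, 10, 2)), c(1, 1, 1))
  mask <- array(1L, dim(g$voxels))
  d <- array(10, dim(g$voxels))
  expect_equal(v_xgy(dose_grid(d, g), mask, 50), 0)    # all below
  expect_equal(v_xgy(dose_grid(d, g), mask, 0), 100)   # threshold 0
  d2 <- d; d2[1:5, , ] <- 80                            # exactly half >= 45
  expect_equal(v_xgy(dose_grid(d2, g), mask, 45), 50)
  # non-increasing in the threshold
  d3 <- array(stats::runif(200, 0, 120), dim(g$voxels))
  vs <- sapply(seq(0, 120, by = 10), function(th)
    v_xgy(dose_grid(d3, g), mask, th))
  expect_true(all(diff(vs) <= 0))
  expect_error(v_xgy(dose_grid(d, g), array(0L, dim(d)), 10), "empty")
})

test_that("dose statistics match direct min/mean/max over the mask", {
  g <- volume_grid(array(0, c(6, 6, 6)), c(1, 1, 1))
  mask <- array(0L, dim(g$voxels)); mask[1:2, 1, 1] <- 1L
  d <- array(0, dim(g$voxels)); d[1, 1, 1] <- 10; d[2, 1, 1] <- 30
  st <- dose_stats(dose_grid(d, g), mask)
  expect_equal(st, c(min = 10, mean = 20, max = 30))
  cst <- dose_stats(dose_grid(array(7, dim(g$voxels)), g),
                    array(1L, dim(g$voxels)))
  expect_equal(cst, c(min = 7, mean = 7, max = 7))
  set.seed(2)
  d2 <- array(stats::runif(216, 0, 150), dim(g$voxels))
  m2 <- array(rbinom(216, 1, 0.4), dim(g$voxels))
  st2 <- dose_stats(dose_grid(d2, g), m2)
  v <- d2[m2 == 1]
  expect_equal(st2, c(min = min(v), mean = mean(v), max = max(v)))
  expect_true(st2[["min"]] <= st2[["mean"]] && st2[["mean"]] <= st2[["max"]])
})

test_that("plan metrics bundle CI, liver V-levels and per-structure stats", {
  case <- small_case()
  dose <- toy_dose(case, case$clinical_angles)
  pm <- plan_metrics(case, dose)
  expect_named(pm$v_tlv, c("V45", "V50"))
  expect_true(all(pm$v_tlv >= 0 & pm$v_tlv <= 100))
  expect_equal(rownames(pm$dose_stats), canonical_structures())
  expect_true(all(pm$dose_stats[, "min"] <= pm$dose_stats[, "mean"]))
  expect_true(all(pm$dose_stats[, "mean"] <= pm$dose_stats[, "max"]))
  expect_equal(pm$dose_stats["PGTV", "mean"], 100)
})
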