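test_that("ray fan has 25 parallel unit-direction rays ending at the isocenter plane", {
  case <- tiny_case()
  for (ang in c(0, 37, 180, 271)) {
    fan <- ray_fan(case, ang)
    expect_length(fan, 25)
    d0 <- fan[[1]]$direction
    expect_equal(sqrt(sum(d0^2)), 1, tolerance = 1e-9)
    expect_equal(fan[[1]]$end, case$isocenter)
    for (r in fan) {
      expect_equal(r$direction, d0)
      expect_equal(r$length / r$n_bins, 0.25)  # 1000 mm / 4000 bins
      # offset lies in the isocenter plane (perpendicular to the beam)
      expect_equal(sum((r$end - case$isocenter) * d0), 0, tolerance = 1e-9)
    }
  }
})

test_that("offsets sit on the 1/3 and 2/3 ellipses of the BEV extents", {
  case <- symmetric_case()  # circular PGTV cross-section
  fan <- ray_fan(case, 90)
  half <- bev_extents(case, 90)
  fr <- baods:::gantry_frame(90)
  offs <- t(vapply(fan[-1], function(r) r$end - case$isocenter, numeric(3)))
  pu <- offs %*% fr$u; pv <- offs %*% fr$v
  rr <- sqrt((pu / half[["half_u"]])^2 + (pv / half[["half_v"]])^2)
  # inner 12 at scaled radius 1/3, outer 12 at 2/3; all within the 2/3 ellipse
  expect_equal(as.numeric(rr), rep(c(1 / 3, 2 / 3), each = 12),
               tolerance = 1e-9)
  # circular cross-section: inner offsets equidistant from the central ray
  dist <- sqrt(rowSums(offs[1:12, ]^2))
  expect_true(diff(range(dist)) < 1e-9 * max(dist))
})

test_that("degenerate PGTV extent falls back to one-voxel radii with warning", {
  case <- tiny_case()
  one <- array(0L, case$volume$shape)
  idx <- which(case$structures$PGTV == 1L, arr.ind = TRUE)[1, , drop = FALSE]
  one[idx] <- 1L
  masks <- lapply(case$structures, identity)
  masks$PGTV <- one
  ax <- baods:::grid_axes(case$volume)
  iso <- sapply(1:3, function(a) ax[[a]][idx[1, a]])
  case1 <- patient_case("degenerate", case$volume,
                        structure_set(masks, case$volume), iso, numeric(0))
  expect_warning(fan <- ray_fan(case1, 0), "degenerate")
  expect_length(fan, 25)
})

test_that("per-patient normalization stats use the population sd with a clamp", {
  # constant volume: sd clamps to 1e-6, normalized values are 0
  v <- volume_grid(array(60, c(4, 4, 2)), c(10, 10, 10), c(0, 0, 0))
  m <- array(1L, c(4, 4, 2))
  ss <- structure_set(setNames(rep(list(m), 8), canonical_structures()), v)
  flat <- patient_case("flat", v, ss, c(20, 20, 10), numeric(0))
  st <- znorm_stats(flat)
  expect_equal(st[["mean"]], 60)
  expect_equal(st[["sd"]], 1e-6)
  ray <- ray_fan(flat, 0, length = 10, n_bins = 4)[[1]]  # interior bins only
  fb <- trace_ray(flat, ray, st)
  expect_equal(fb[1, ], rep(0, 4))
  # non-degenerate: normalized volume has mean 0, sd 1
  case <- small_case()
  st2 <- znorm_stats(case)
  z <- (case$volume$voxels - st2[["mean"]]) / st2[["sd"]]
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)
  # population (not sample) sd of a two-value set {0, 2} is 1
  vv <- c(0, 2)
  expect_equal(sqrt(mean((vv - mean(vv))^2)), 1)
  expect_error(trace_ray(case, ray_fan(case, 0)[[1]],
                         c(mean = 0, sd = 1e-9)), "znorm")
})

test_that("traced rays match a per-bin voxel-lookup oracle", {
  case <- tiny_case()
  st <- znorm_stats(case)
  g <- case$volume
  for (ang in c(20, 200)) {
    ray <- ray_fan(case, ang, n_bins = 4000)[[7]]
    fb <- trace_ray(case, ray, st)
    expect_equal(dim(fb), c(9L, 4000L))
    # independent oracle: explicit per-bin interpolation/lookup
    start <- ray$end - ray$length * ray$direction
    for (k in sample(1:4000, 60)) {
      p <- start + (k - 0.5) * (ray$length / 4000) * ray$direction
      u <- (p - g$origin) / g$spacing + 0.5
      i0 <- floor(u); fr <- u - i0
      acc <- 0
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        ii <- i0 + c(a, b, cc)
        w <- prod(ifelse(c(a, b, cc) == 1, fr, 1 - fr))
        val <- if (all(ii >= 1 & ii <= g$shape))
          g$voxels[ii[1], ii[2], ii[3]] else -1000
        acc <- acc + w * val
      }
      expect_equal(fb[1, k], (acc - st[["mean"]]) / st[["sd"]],
                   tolerance = 1e-9)
      nn <- round(u)
      for (f in 1:8) {
        mv <- if (all(nn >= 1 & nn <= g$shape))
          case$structures[[f]][nn[1], nn[2], nn[3]] else 0L
        expect_identical(as.integer(fb[f + 1, k]), as.integer(mv))
      }
    }
  }
})

test_that("a ray through air reads -1000 HU and zero masks", {
  case <- tiny_case()
  st <- c(mean = 0, sd = 1)
  # vertical ray far outside the body
  ray <- list(end = case$isocenter + c(0, 0, 5000),
              direction = c(0, 0, 1), length = 100, n_bins = 16)
  fb <- trace_ray(case, ray, st)
  expect_equal(fb[1, ], rep(-1000, 16))
  expect_equal(as.vector(fb[2:9, ]), rep(0, 8 * 16))
})

test_that("feature tensor layout is feature-fastest, then ray, then angle", {
  case <- tiny_case()
  ft <- build_feature_tensor(case, angle_step = 90, n_bins = 30)
  expect_equal(dim(ft$values), c(4 * 225L, 30L))
  expect_equal(ft$angles, c(0, 90, 180, 270))
  st <- znorm_stats(case)
  for (a in c(0L, 3L)) for (r in c(0L, 1L, 24L)) {
    fan <- ray_fan(case, ft$angles[a + 1], n_bins = 30)
    fb <- trace_ray(case, fan[[r + 1]], st)
    for (f in 0:8)
      expect_equal(ft$values[a * 225L + r * 9L + f + 1L, ], fb[f + 1, ])
  }
})

test_that("single-angle tensors have 225 rows and binary structure rows", {
  case <- tiny_case()
  ft <- build_feature_tensor(case, angle_step = 360, n_bins = 25)
  expect_equal(nrow(ft$values), 225L)
  bin_rows <- setdiff(seq_len(225L), seq(1L, 225L, by = 9L))
  expect_true(all(ft$values[bin_rows, ] %in% c(0, 1)))
  expect_error(build_feature_tensor(case, angle_step = 7), "divide")
})

test_that("rotating the phantom shifts the angle axis of the tensor", {
  base <- generate_case(phantom_config(shape = c(48, 48, 24),
                                       spacing = c(8, 8, 8),
                                       noise_sd = 0, seed = 21))
  rot <- generate_case(phantom_config(shape = c(48, 48, 24),
                                      spacing = c(8, 8, 8),
                                      noise_sd = 0, seed = 21,
                                      rotation_deg = 45))
  fa <- build_feature_tensor(base, angle_step = 45, n_bins = 40)
  fb <- build_feature_tensor(rot, angle_step = 45, n_bins = 40)
  # block for angle a in the rotated phantom ~ block for angle a - 45 in the
  # base phantom (rigid rotation, up to voxelization of masks and isocenter)
  shifted <- fb$values[c(226:1800, 1:225), ]
  agree <- mean(abs(fa$values - shifted) < 0.35)
  expect_gt(agree, 0.9)
})
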