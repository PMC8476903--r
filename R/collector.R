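# Beam's-eye-view ray collector: 25 parallel rays per gantry angle, each
# sampling 9 features (normalized HU + 8 structure masks) in 4000 bins over
# a fixed 1000 mm span ending in the isocenter plane.

#' Half-extents of the PGTV cross-section in the beam's eye view
#'
#' Projects all PGTV voxel centers onto the in-plane BEV axes (u: in the
#' axial rotation plane, v: patient superior) and returns half the extent of
#' the axis-aligned bounding box along each. Degenerate extents (single
#' voxel column) fall back to one voxel with a warning.
#'
#' @param case a [patient_case()].
#' @param gantry_deg gantry angle in degrees.
#' @return named numeric: `half_u`, `half_v` in mm.
#' @export
bev_extents <- function(case, gantry_deg) {
  fr <- gantry_frame(gantry_deg)
  idx <- which(case$structures$PGTV == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("PGTV mask is empty")
  g <- case$volume
  pts <- cbind(g$origin[1] + (idx[, 1] - 0.5) * g$spacing[1],
               g$origin[2] + (idx[, 2] - 0.5) * g$spacing[2],
               g$origin[3] + (idx[, 3] - 0.5) * g$spacing[3])
  rel <- sweep(pts, 2, case$isocenter)
  pu <- rel %*% fr$u
  pv <- rel %*% fr$v
  half <- c(half_u = (max(pu) - min(pu)) / 2,
            half_v = (max(pv) - min(pv)) / 2)
  fallback <- max(g$spacing)
  if (any(half <= 0)) {
    warning("degenerate PGTV BEV extent; falling back to 1-voxel radii")
    half[half <= 0] <- fallback
  }
  half
}

#' Build the 25-ray fan for one gantry angle
#'
#' Ray 1 is the central ray through the isocenter along the beam direction.
#' The remaining 24 rays are parallel offsets placed at 30 deg angular steps
#' (starting at BEV "up", the patient-superior direction) on two ellipses
#' whose semi-axes are 1/3 (inner 12) and 2/3 (outer 12) of the PGTV BEV
#' half-extents. Every ray is `length` mm long and ends in the isocenter
#' plane, source side first.
#'
#' @param case a [patient_case()].
#' @param gantry_deg gantry angle in degrees.
#' @param length ray length in mm (default 1000).
#' @param n_bins number of sampling bins (default 4000; the default pitch is
#'   0.25 mm).
#' @return list of 25 rays, each `list(end, direction, length, n_bins)`;
#'   `end` is the isocenter-plane endpoint (mm), `direction` the unit beam
#'   travel vector.
#' @export
ray_fan <- function(case, gantry_deg, length = 1000, n_bins = 4000) {
  fr <- gantry_frame(gantry_deg)
  half <- bev_extents(case, gantry_deg)
  phis <- (0:11) * 30 * pi / 180
  mk <- function(end) list(end = end, direction = fr$d,
                           length = length, n_bins = as.integer(n_bins))
  rays <- vector("list", 25L)
  rays[[1]] <- mk(case$isocenter)
  k <- 2L
  for (s in c(1 / 3, 2 / 3)) {
    a <- s * half[["half_u"]]
    b <- s * half[["half_v"]]
    for (phi in phis) {
      off <- a * sin(phi) * fr$u + b * cos(phi) * fr$v
      rays[[k]] <- mk(case$isocenter + off)
      k <- k + 1L
    }
  }
  rays
}

#' Per-patient HU normalization statistics
#'
#' Mean and population standard deviation of all voxels of the patient
#' volume (Z-score normalization is per patient; only the HU channel is
#' normalized). The sd is clamped below at 1e-6 so constant volumes
#' normalize to zero instead of dividing by zero.
#'
#' @param case a [patient_case()].
#' @return named numeric: `mean`, `sd`.
#' @export
znorm_stats <- function(case) {
  v <- case$volume$voxels
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  c(mean = m, sd = max(s, 1e-6))
}

# bin-center room coordinates of a ray, source side -> isocenter (n_bins x 3)
ray_bin_centers <- function(ray) {
  pitch <- ray$length / ray$n_bins
  s <- (seq_len(ray$n_bins) - 0.5) * pitch
  start <- ray$end - ray$length * ray$direction
  cbind(start[1] + s * ray$direction[1],
        start[2] + s * ray$direction[2],
        start[3] + s * ray$direction[3])
}

#' Sample one ray: 9 features x n_bins
#'
#' Row 1 is the Z-score-normalized HU (trilinear interpolation; bins outside
#' the volume read air, -1000 HU, before normalization). Rows 2-9 are the
#' eight structure masks in canonical order, sampled nearest-voxel so they
#' remain exactly binary; outside the volume they read 0.
#'
#' @param case a [patient_case()].
#' @param ray a ray from [ray_fan()].
#' @param hu_stats named numeric `c(mean =, sd =)` from [znorm_stats()] of
#'   the same case.
#' @return 9 x n_bins numeric matrix, bins ordered source side ->
#'   isocenter.
#' @export
trace_ray <- function(case, ray, hu_stats = znorm_stats(case)) {
  if (hu_stats[["sd"]] < 1e-6)
    stop("hu_stats sd below 1e-6; use znorm_stats(), which clamps the sd")
  pts <- ray_bin_centers(ray)
  out <- matrix(0, 9L, ray$n_bins)
  hu <- sample_trilinear(case$volume, pts, outside = -1000)
  out[1, ] <- (hu - hu_stats[["mean"]]) / hu_stats[["sd"]]
  for (f in 1:8)
    out[f + 1L, ] <- sample_nearest(case$structures[[f]], case$volume, pts,
                                    outside = 0)
  out
}

#' Assemble the network input feature tensor
#'
#' Samples the 25-ray fan at every gantry angle from 0 deg up in steps of
#' `angle_step` and stacks the per-ray 9 x n_bins blocks into one matrix.
#' Row `a*225 + r*9 + f` (all 0-based) holds feature `f` of ray `r` at angle
#' index `a` — feature fastest, then ray, then angle, matching the stride-9
#' and stride-25 merging convolutions. With the defaults (2 deg steps, 180
#' angles) the tensor is 40500 x 4000. Normalization statistics are computed
#' once per case; the binary structure rows are never normalized.
#'
#' @param case a [patient_case()].
#' @param angle_step step between sampled gantry angles in degrees; must
#'   divide 360 (default 2).
#' @param n_bins bins per ray (default 4000).
#' @param ray_length ray length in mm (default 1000).
#' @return object of class `baods_features`: list with `values`
#'   (matrix rows x n_bins), `angles`, `case_id`, `n_rays`, `n_features`.
#' @export
build_feature_tensor <- function(case, angle_step = 2, n_bins = 4000,
                                 ray_length = 1000) {
  if (360 %% angle_step != 0)
    stop("angle_step must divide 360")
  angles <- seq(0, 360 - angle_step, by = angle_step)
  stats <- znorm_stats(case)
  n_ang <- length(angles)
  block_rows <- 25L * 9L
  values <- matrix(0, n_ang * block_rows, n_bins)
  masks <- case$structures
  for (ai in seq_len(n_ang)) {
    rays <- ray_fan(case, angles[ai], length = ray_length, n_bins = n_bins)
    pts <- do.call(rbind, lapply(rays, ray_bin_centers))
    hu <- matrix(sample_trilinear(case$volume, pts, outside = -1000),
                 nrow = n_bins)                      # n_bins x 25
    hu <- (hu - stats[["mean"]]) / stats[["sd"]]
    mk <- lapply(1:8, function(f)
      matrix(sample_nearest(masks[[f]], case$volume, pts, outside = 0),
             nrow = n_bins))
    base <- (ai - 1L) * block_rows
    for (r in 1:25) {
      row0 <- base + (r - 1L) * 9L
      values[row0 + 1L, ] <- hu[, r]
      for (f in 1:8)
        values[row0 + 1L + f, ] <- mk[[f]][, r]
    }
  }
  structure(list(values = values, angles = angles,
                 case_id = case$case_id, n_rays = 25L, n_features = 9L,
                 n_bins = as.integer(n_bins)),
            class = "baods_features")
}

#' @export
print.baods_features <- function(x, ...) {
  cat(sprintf(
    "<baods_features> %s: %d x %d (%d angles x 25 rays x 9 features)\n",
    x$case_id, nrow(x$values), ncol(x$values), length(x$angles)))
  invisible(x)
}
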