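# Synthetic abdominal phantom generator: ellipsoidal organs on a voxel
# grid, geometry-derived "clinical" angles, and a toy dose model, so the
# whole pipeline is exercisable without patient data.

#' Phantom configuration
#'
#' Describes an abdominal phantom as eight ellipsoidal structures (center,
#' semi-axes in mm, HU value, optional rotation about the patient axis).
#' The defaults emulate a liver case: soft-tissue body (40 HU), liver
#' (60 HU) containing the tumor (55 HU), hollow organs at 30 HU, heart 45,
#' spleen 50, air -1000 outside the body. `rotation_deg` rotates the whole
#' anatomy rigidly about the patient's longitudinal axis, which shifts the
#' geometry-derived reference angles by the same amount — the learnable
#' structure the training smoke tests rely on.
#'
#' @param shape voxel counts (nx, ny, nz); default c(96, 96, 48).
#' @param spacing voxel size mm; default c(4, 4, 4).
#' @param rotation_deg rigid rotation of the anatomy about z (default 0).
#' @param tumor_offset PGTV center offset from the liver center, mm (before
#'   rotation; default c(18, 8, 4)).
#' @param noise_sd HU noise standard deviation inside the body (default 10;
#'   voxel values are rounded to integer CT numbers).
#' @param seed RNG seed fixing all randomness (default 1).
#' @param organs optional named list overriding per-organ
#'   `list(center, semi, hu)` entries; an optional `rot` field rotates that
#'   organ's ellipsoid about the patient axis (degrees, on top of
#'   `rotation_deg`).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 48), spacing = c(4, 4, 4),
                           rotation_deg = 0, tumor_offset = c(18, 8, 4),
                           noise_sd = 10, seed = 1, organs = list()) {
  base <- list(
    body      = list(center = c(0, 0, 0),     semi = c(150, 105, 110), hu = 40),
    TLV       = list(center = c(-55, -15, 5), semi = c(62, 50, 48),    hu = 60),
    PGTV      = list(center = NULL,           semi = c(20, 16, 16),    hu = 55),
    duodenum  = list(center = c(-5, 25, -25), semi = c(14, 12, 22),    hu = 30),
    stomach   = list(center = c(35, -5, 8),   semi = c(38, 28, 26),    hu = 30),
    esophagus = list(center = c(0, 25, 60),   semi = c(9, 9, 34),      hu = 30),
    heart     = list(center = c(15, -35, 62), semi = c(30, 26, 26),    hu = 45),
    spleen    = list(center = c(65, 15, 12),  semi = c(24, 18, 28),    hu = 50))
  for (nm in names(organs))
    base[[nm]] <- utils::modifyList(base[[nm]], organs[[nm]])
  if (is.null(base$PGTV$center))
    base$PGTV$center <- base$TLV$center + tumor_offset
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 rotation_deg = rotation_deg, noise_sd = noise_sd,
                 seed = as.integer(seed), organs = base),
            class = "phantom_config")
}

# rotate a point about the z axis (degrees)
rot_z <- function(p, deg) {
  th <- deg * pi / 180
  c(cos(th) * p[1] - sin(th) * p[2],
    sin(th) * p[1] + cos(th) * p[2], p[3])
}

# binary mask of an ellipsoid (rotated about z) on the grid axes
ellipsoid_mask <- function(axes, center, semi, rot_deg = 0) {
  nx <- length(axes[[1]]); ny <- length(axes[[2]]); nz <- length(axes[[3]])
  th <- rot_deg * pi / 180
  dx <- rep(axes[[1]] - center[1], times = ny * nz)
  dy <- rep(rep(axes[[2]] - center[2], each = nx), times = nz)
  dz <- rep(axes[[3]] - center[3], each = nx * ny)
  xr <- (cos(th) * dx + sin(th) * dy) / semi[1]
  yr <- (-sin(th) * dx + cos(th) * dy) / semi[2]
  zr <- dz / semi[3]
  array(as.integer(xr^2 + yr^2 + zr^2 <= 1), dim = c(nx, ny, nz))
}

#' Generate a synthetic phantom case
#'
#' Rasterizes the configured ellipsoids into binary masks, paints the HU
#' volume (air -1000 outside the body; organ HU plus rounded Gaussian noise
#' inside), places the isocenter at the PGTV centroid, and derives the
#' "clinical" gantry angles from the geometry via
#' [geometric_reference_angles()]. The same seed always reproduces the same
#' case. Containment (PGTV within liver within body; every OAR within the
#' body) is validated and violations raise an error.
#'
#' @param config a [phantom_config()].
#' @return a [patient_case()].
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  fov <- config$shape * config$spacing
  origin <- -fov / 2
  axes <- lapply(1:3, function(a)
    origin[a] + (seq_len(config$shape[a]) - 0.5) * config$spacing[a])
  rot <- config$rotation_deg
  masks <- lapply(config$organs, function(o)
    ellipsoid_mask(axes, rot_z(o$center, rot), o$semi,
                   rot_deg = rot + (o$rot %||% 0)))
  # containment invariants
  contain <- function(inner, outer, what)
    if (any(masks[[inner]] > masks[[outer]]))
      stop(what, ": '", inner, "' is not contained in '", outer, "'")
  contain("PGTV", "TLV", "phantom containment violated")
  contain("TLV", "body", "phantom containment violated")
  for (nm in c("duodenum", "stomach", "esophagus", "heart", "spleen"))
    contain(nm, "body", "phantom containment violated")

  hu <- array(-1000, dim = config$shape)
  paint <- c("body", "TLV", "duodenum", "stomach", "esophagus", "heart",
             "spleen", "PGTV")  # PGTV last so the tumor HU wins inside TLV
  for (nm in paint)
    hu[masks[[nm]] == 1L] <- config$organs[[nm]]$hu
  inside <- masks$body == 1L
  if (config$noise_sd > 0)
    hu[inside] <- hu[inside] + stats::rnorm(sum(inside), 0, config$noise_sd)
  hu <- round(hu)

  grid <- volume_grid(hu, config$spacing, origin)
  ss <- structure_set(masks, grid)
  idx <- which(masks$PGTV == 1L, arr.ind = TRUE)
  iso <- sapply(1:3, function(a) mean(axes[[a]][idx[, a]]))
  case <- patient_case(
    case_id = sprintf("phantom-seed%d-rot%g", config$seed, rot),
    volume = grid, structures = ss, isocenter = iso,
    clinical_angles = numeric(0))
  case$clinical_angles <- as.numeric(geometric_reference_angles(case))
  case
}

#' Geometric per-angle scores over 0..359 degrees
#'
#' Scores each gantry angle along its central ray through the isocenter:
#' minus the water-equivalent path length (WEPL, relative stopping power
#' approximated as `max(0, 1 + HU/1000)`) from the body entry to the
#' proximal PGTV edge, minus `lambda` times the organ-at-risk path length
#' downstream of the distal PGTV edge. Scores are min-max normalized to
#' \[0, 1\]; an all-tie profile maps to a constant 0.5.
#'
#' @param case a [patient_case()].
#' @param lambda OAR penalty weight per mm (default 2).
#' @param step_mm sampling step along the ray (default 1).
#' @param reach half-length of the sampled ray segment, mm (default 250).
#' @return numeric vector of length 360 in \[0, 1\].
#' @export
geometric_sbeam <- function(case, lambda = 2, step_mm = 1, reach = 250) {
  if (sum(case$structures$PGTV) == 0L) stop("PGTV mask is empty")
  tvals <- seq(-reach, reach, by = step_mm)
  nt <- length(tvals)
  oars <- c("duodenum", "stomach", "esophagus", "heart", "spleen")
  scores <- numeric(360)
  for (ang in 0:359) {
    d <- gantry_frame(ang)$d
    pts <- cbind(case$isocenter[1] + tvals * d[1],
                 case$isocenter[2] + tvals * d[2],
                 case$isocenter[3] + tvals * d[3])
    body <- sample_nearest(case$structures$body, case$volume, pts)
    pgtv <- sample_nearest(case$structures$PGTV, case$volume, pts)
    oar <- rep(0, nt)
    for (nm in oars)
      oar <- pmax(oar, sample_nearest(case$structures[[nm]], case$volume,
                                      pts))
    if (!any(pgtv > 0) || !any(body > 0)) {
      scores[ang + 1L] <- -Inf
      next
    }
    i_entry <- which(body > 0)[1]
    i_prox <- which(pgtv > 0)[1]
    i_dist <- max(which(pgtv > 0))
    wepl <- 0
    if (i_prox > i_entry) {
      seg <- i_entry:(i_prox - 1L)
      hu <- sample_trilinear(case$volume, pts[seg, , drop = FALSE])
      wepl <- sum(pmax(0, 1 + hu / 1000)) * step_mm
    }
    l_oar <- 0
    if (i_dist < nt) {
      seg <- (i_dist + 1L):nt
      l_oar <- sum(oar[seg] * body[seg]) * step_mm
    }
    scores[ang + 1L] <- -wepl - lambda * l_oar
  }
  if (any(!is.finite(scores)))
    scores[!is.finite(scores)] <- min(scores[is.finite(scores)]) - 1
  rng <- range(scores)
  if (diff(rng) == 0) return(rep(0.5, 360))
  (scores - rng[1]) / diff(rng)
}

#' Geometry-derived reference angles for a phantom
#'
#' Surrogate for planner-chosen angles: applies the constrained top-n
#' selection rule ([select_angles()]) to the geometric scores of
#' [geometric_sbeam()].
#'
#' @param case a [patient_case()].
#' @param n number of angles (default 3).
#' @param min_sep minimum pairwise circular separation in degrees
#'   (default 30).
#' @param ... passed to [geometric_sbeam()].
#' @return numeric vector of `n` gantry angles in degrees, with the
#'   normalized score vector attached as attribute `"scores"`.
#' @export
geometric_reference_angles <- function(case, n = 3, min_sep = 30, ...) {
  s <- geometric_sbeam(case, ...)
  ang <- select_angles(s, k = n, min_sep = min_sep)
  attr(ang, "scores") <- s
  ang
}

#' Toy dose model for plan-metric testing
#'
#' Deposits, for each field, one dose unit in the cylinder swept along the
#' beam through the PGTV beam's-eye-view ellipse (plus a lateral margin),
#' from the body entry down to the distal PGTV edge plus a distal margin;
#' zero beyond. Fields are summed with weight one and the total is
#' normalized so the mean PGTV dose is 100%. This is a geometric stand-in
#' for a dose engine, not a proton transport model.
#'
#' @param case a [patient_case()].
#' @param angles gantry angles of the fields (>= 1).
#' @param margin lateral and distal margin in mm (default 5).
#' @param prescription_level % isodose level stored on the result
#'   (default 100).
#' @return a [dose_grid()] in % of prescription.
#' @export
toy_dose <- function(case, angles, margin = 5, prescription_level = 100) {
  if (!length(angles)) stop("at least one beam angle is required")
  g <- case$volume
  axes <- grid_axes(g)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  dx <- rep(axes[[1]] - case$isocenter[1], times = ny * nz)
  dy <- rep(rep(axes[[2]] - case$isocenter[2], each = nx), times = nz)
  dz <- rep(axes[[3]] - case$isocenter[3], each = nx * ny)
  body <- as.vector(case$structures$body) == 1L
  pgtv <- as.vector(case$structures$PGTV) == 1L
  total <- numeric(nx * ny * nz)
  for (ang in angles) {
    fr <- gantry_frame(ang)
    pu <- dx * fr$u[1] + dy * fr$u[2] + dz * fr$u[3]
    pv <- dx * fr$v[1] + dy * fr$v[2] + dz * fr$v[3]
    tt <- dx * fr$d[1] + dy * fr$d[2] + dz * fr$d[3]
    half <- bev_extents(case, ang)
    lat <- (pu / (half[["half_u"]] + margin))^2 +
           (pv / (half[["half_v"]] + margin))^2 <= 1
    t_dist <- max(tt[pgtv])
    field <- body & lat & (tt <= t_dist + margin)
    if (!any(field & pgtv))
      stop("beam at angle ", ang, " misses the PGTV entirely")
    total <- total + as.numeric(field)
  }
  mean_pgtv <- mean(total[pgtv])
  if (mean_pgtv <= 0) stop("no PGTV coverage; cannot normalize")
  dose <- array(total / mean_pgtv * 100, dim = g$shape)
  dose_grid(dose, g, prescription_level = prescription_level)
}
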