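#' Voxel volume with spacing and origin
#'
#' A `volume_grid` holds a 3D array of CT numbers (Hounsfield units) together
#' with its geometry: per-axis voxel size in mm and the room-coordinate
#' position of the corner of voxel (1,1,1). Voxel centers therefore sit at
#' `origin + (i - 0.5) * spacing` for 1-based index `i`. Room coordinates
#' follow the DICOM patient system (x to patient left, y posterior,
#' z superior), all in mm.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, mm position of the corner of the first
#'   voxel.
#' @return an object of class `volume_grid` with fields `voxels`, `spacing`,
#'   `origin`, `shape`.
#' @export
volume_grid <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("all HU values must be finite")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         shape = dim(voxels)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, HU range [%g, %g]\n",
              paste(format(x$origin), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# continuous 1-based voxel-center coordinates of room points (n x 3)
world_to_cont <- function(grid, pts) {
  pts <- rbind(pts)
  cbind((pts[, 1] - grid$origin[1]) / grid$spacing[1] + 0.5,
        (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 0.5,
        (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 0.5)
}

# room-coordinate centers of all voxels, as three vectors
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * grid$spacing[a])
}

#' Trilinear sampling of a volume at room-coordinate points
#'
#' Points outside the volume (any neighbour voxel out of range) draw the
#' `outside` value for the missing corners, so a point fully outside returns
#' `outside` exactly.
#'
#' @param grid a [volume_grid()].
#' @param pts n x 3 matrix of room coordinates (mm).
#' @param outside value assumed beyond the volume (default -1000, air).
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(grid, pts, outside = -1000) {
  u <- world_to_cont(grid, pts)
  arr <- grid$voxels
  dm <- grid$shape
  i0 <- floor(u)
  tf <- u - i0
  n <- nrow(u)
  val <- numeric(n)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ii <- i0[, 1] + a; jj <- i0[, 2] + b; kk <- i0[, 3] + cc
    w <- (if (a) tf[, 1] else 1 - tf[, 1]) *
         (if (b) tf[, 2] else 1 - tf[, 2]) *
         (if (cc) tf[, 3] else 1 - tf[, 3])
    ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
    v <- rep(outside, n)
    if (any(ok))
      v[ok] <- arr[cbind(ii[ok], jj[ok], kk[ok])]
    val <- val + w * v
  }
  val
}

#' Nearest-voxel sampling of a (mask) array at room-coordinate points
#'
#' @param arr 3D array aligned to `grid` (typically a binary mask).
#' @param grid a [volume_grid()] giving the geometry.
#' @param pts n x 3 matrix of room coordinates (mm).
#' @param outside value returned beyond the volume (default 0).
#' @return numeric vector of length n.
#' @export
sample_nearest <- function(arr, grid, pts, outside = 0) {
  u <- world_to_cont(grid, pts)
  dm <- grid$shape
  ii <- round(u[, 1]); jj <- round(u[, 2]); kk <- round(u[, 3])
  ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
  v <- rep(outside, nrow(u))
  if (any(ok))
    v[ok] <- arr[cbind(ii[ok], jj[ok], kk[ok])]
  v
}

#' Canonical structure order for the eight abdominal structures
#'
#' The fixed structure order used throughout: body, total liver volume (TLV),
#' primary gross tumor volume (PGTV), then the organs at risk duodenum,
#' stomach, esophagus, heart, spleen.
#'
#' @return character vector of the 8 canonical names.
#' @export
canonical_structures <- function() {
  c("body", "TLV", "PGTV", "duodenum", "stomach", "esophagus",
    "heart", "spleen")
}

#' Ordered set of binary structure masks
#'
#' @param masks named list of 3D arrays with values in {0,1}, one per
#'   canonical structure (any order; reordered canonically).
#' @param grid the [volume_grid()] the masks are aligned to.
#' @return object of class `structure_set`: a named list of integer arrays in
#'   canonical order.
#' @export
structure_set <- function(masks, grid) {
  canon <- canonical_structures()
  missing <- setdiff(canon, names(masks))
  if (length(missing))
    stop("missing canonical structures: ", paste(missing, collapse = ", "))
  out <- lapply(canon, function(nm) {
    m <- masks[[nm]]
    if (!identical(dim(m), grid$shape))
      stop("mask '", nm, "' shape does not match grid")
    if (!all(m %in% c(0, 1)))
      stop("mask '", nm, "' must be binary")
    array(as.integer(m), dim = grid$shape)
  })
  names(out) <- canon
  structure(out, class = "structure_set")
}

#' Patient case container
#'
#' Bundles the CT volume, the eight structure masks, the isocenter and the
#' clinically planned gantry angles for one patient (or phantom).
#'
#' @param case_id character identifier.
#' @param volume a [volume_grid()].
#' @param structures a [structure_set()] aligned to `volume`.
#' @param isocenter room-coordinate point (mm); must fall inside the PGTV
#'   bounding box.
#' @param clinical_angles gantry angles in degrees, each in \[0, 360);
#'   three for a double-scattering plan, but any count >= 0 is stored.
#' @return object of class `patient_case`.
#' @export
patient_case <- function(case_id, volume, structures, isocenter,
                         clinical_angles) {
  stopifnot(inherits(volume, "volume_grid"),
            inherits(structures, "structure_set"))
  isocenter <- as.numeric(isocenter)
  clinical_angles <- as.numeric(clinical_angles)
  if (length(clinical_angles) &&
      (any(clinical_angles < 0) || any(clinical_angles >= 360)))
    stop("clinical angles must lie in [0, 360)")
  pg <- structures$PGTV
  if (sum(pg) > 0) {
    ax <- grid_axes(volume)
    idx <- which(pg == 1L, arr.ind = TRUE)
    lo <- sapply(1:3, function(a) ax[[a]][min(idx[, a])] -
                   volume$spacing[a] / 2)
    hi <- sapply(1:3, function(a) ax[[a]][max(idx[, a])] +
                   volume$spacing[a] / 2)
    if (any(isocenter < lo) || any(isocenter > hi))
      stop("isocenter lies outside the PGTV bounding box")
  }
  structure(
    list(case_id = as.character(case_id), volume = volume,
         structures = structures, isocenter = isocenter,
         clinical_angles = clinical_angles),
    class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s\n", x$case_id))
  print(x$volume)
  vv <- prod(x$volume$spacing) / 1000  # cm^3
  for (nm in names(x$structures))
    cat(sprintf("  %-10s %8.1f cm^3\n", nm, sum(x$structures[[nm]]) * vv))
  cat(sprintf("  isocenter (%s) mm; clinical angles: %s\n",
              paste(format(x$isocenter), collapse = ", "),
              if (length(x$clinical_angles))
                paste(x$clinical_angles, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Dose grid in percent of prescription
#'
#' @param dose 3D array, same shape as its reference grid, in % of the
#'   prescription dose; non-negative.
#' @param grid the reference [volume_grid()].
#' @param prescription_level the % isodose level defining the prescribed
#'   isodose surface (default 100).
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(dose, grid, prescription_level = 100) {
  if (!identical(dim(dose), grid$shape))
    stop("dose shape does not match reference grid")
  if (any(dose < 0) || any(!is.finite(dose)))
    stop("dose must be finite and non-negative")
  structure(list(dose = dose, grid = grid,
                 prescription_level = prescription_level),
            class = "dose_grid")
}

# gantry angle (deg, IEC 61217, 0 = beam entering from anterior) ->
# orthonormal frame: d = beam travel direction, u/v = BEV in-plane axes
# (v = patient superior = BEV "up")
gantry_frame <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  list(d = c(-sin(g), cos(g), 0),
       u = c(cos(g), sin(g), 0),
       v = c(0, 0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# circular distance between angles in degrees
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
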