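# Planar contour <-> binary mask conversion. Contours are polygons in room
# coordinates (mm) on a single axial slice. Filling uses the even-odd rule
# evaluated at voxel centers, the standard RTSTRUCT semantics; extraction
# traces the exact voxel-edge boundary, so extract-then-fill reproduces the
# mask voxel-for-voxel.

# even-odd fill of polygons (list of n x 2 matrices, mm) on one slice
rasterize_polygons_slice <- function(polys, xc, yc) {
  nx <- length(xc); ny <- length(yc)
  mask <- matrix(0L, nx, ny)
  if (!length(polys)) return(mask)
  # gather all edges
  ex1 <- ey1 <- ex2 <- ey2 <- numeric(0)
  for (p in polys) {
    if (nrow(p) < 3) next
    x1 <- p[, 1]; y1 <- p[, 2]
    x2 <- c(p[-1, 1], p[1, 1]); y2 <- c(p[-1, 2], p[1, 2])
    ex1 <- c(ex1, x1); ey1 <- c(ey1, y1); ex2 <- c(ex2, x2); ey2 <- c(ey2, y2)
  }
  keep <- ey1 != ey2  # horizontal edges never cross a scanline
  ex1 <- ex1[keep]; ey1 <- ey1[keep]; ex2 <- ex2[keep]; ey2 <- ey2[keep]
  if (!length(ex1)) return(mask)
  for (j in seq_len(ny)) {
    y <- yc[j]
    cross <- (ey1 <= y & y < ey2) | (ey2 <= y & y < ey1)
    if (!any(cross)) next
    xint <- ex1[cross] +
      (y - ey1[cross]) * (ex2[cross] - ex1[cross]) / (ey2[cross] - ey1[cross])
    nbelow <- findInterval(xc, sort(xint))
    mask[, j] <- as.integer(nbelow %% 2L == 1L)
  }
  mask
}

#' Rasterize closed planar contours into a binary volume
#'
#' @param contours list of polygons, each an n x 3 matrix of room
#'   coordinates (mm) on a single axial (constant z) plane.
#' @param grid the target [volume_grid()].
#' @return binary integer array of the grid's shape (even-odd fill at voxel
#'   centers; contours on the same slice toggle each other, so holes work).
#' @export
contours_to_mask <- function(contours, grid) {
  ax <- grid_axes(grid)
  mask <- array(0L, grid$shape)
  if (!length(contours)) return(mask)
  zs <- vapply(contours, function(p) p[1, 3], numeric(1))
  ks <- vapply(zs, function(z) which.min(abs(ax[[3]] - z)), integer(1))
  for (k in unique(ks)) {
    polys <- lapply(contours[ks == k], function(p) p[, 1:2, drop = FALSE])
    mask[, , k] <- rasterize_polygons_slice(polys, ax[[1]], ax[[2]])
  }
  mask
}

# trace the voxel-edge boundary loops of one binary slice. Coordinates are
# voxel-corner positions in mm. Returns a list of m x 2 matrices.
trace_slice_boundary <- function(sl, x0, y0, dx, dy) {
  nx <- nrow(sl); ny <- ncol(sl)
  inside <- function(i, j)
    i >= 1 && i <= nx && j >= 1 && j <= ny && sl[i, j] == 1L
  # directed segments on corner lattice, keyed by start corner "i,j"
  # (corner (i,j) = mm point (x0 + i*dx, y0 + j*dy), i in 0..nx)
  segs <- new.env(parent = emptyenv())
  add_seg <- function(from, to) {
    key <- paste(from, collapse = ",")
    lst <- if (exists(key, segs)) get(key, segs) else list()
    lst[[length(lst) + 1L]] <- to
    assign(key, lst, segs)
  }
  ij <- which(sl == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    if (!inside(i, j - 1L)) add_seg(c(i - 1L, j - 1L), c(i, j - 1L))
    if (!inside(i + 1L, j)) add_seg(c(i, j - 1L), c(i, j))
    if (!inside(i, j + 1L)) add_seg(c(i, j), c(i - 1L, j))
    if (!inside(i - 1L, j)) add_seg(c(i - 1L, j), c(i - 1L, j - 1L))
  }
  loops <- list()
  repeat {
    keys <- ls(segs)
    if (!length(keys)) break
    start <- as.integer(strsplit(keys[1], ",")[[1]])
    loop <- list(start)
    cur <- start
    repeat {
      key <- paste(cur, collapse = ",")
      lst <- get(key, segs)
      nxt <- lst[[1]]
      if (length(lst) == 1L) rm(list = key, envir = segs)
      else assign(key, lst[-1], segs)
      if (all(nxt == start)) break
      loop[[length(loop) + 1L]] <- nxt
      cur <- nxt
    }
    pts <- do.call(rbind, loop)
    loops[[length(loops) + 1L]] <-
      cbind(x0 + pts[, 1] * dx, y0 + pts[, 2] * dy)
  }
  loops
}

#' Extract closed planar contours from a binary mask volume
#'
#' Traces the exact voxel-edge boundary of the mask on every axial slice,
#' producing closed polygons whose even-odd fill at voxel centers
#' reproduces the mask exactly.
#'
#' @param mask binary 3D array.
#' @param grid the [volume_grid()] the mask is aligned to.
#' @return list of n x 3 polygon matrices (mm), one per boundary loop.
#' @export
mask_to_contours <- function(mask, grid) {
  ax <- grid_axes(grid)
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  out <- list()
  for (k in seq_len(grid$shape[3])) {
    sl <- mask[, , k]
    if (!any(sl == 1L)) next
    loops <- trace_slice_boundary(sl, x0, y0, dx, dy)
    z <- ax[[3]][k]
    for (lp in loops)
      out[[length(out) + 1L]] <- cbind(lp, z)
  }
  out
}
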