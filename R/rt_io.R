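# DICOM-RT readers and writers over the minimal codec: a CT series, an
# RTSTRUCT with the eight canonical structures, an RTPLAN carrying the
# gantry angles and isocenter, and a multiframe RTDOSE.

#' Default structure-name alias table
#'
#' Case-insensitive aliases mapping clinical ROI names onto the eight
#' canonical structure names. Extend or override by passing a modified copy
#' to [read_case()].
#'
#' @return named list: canonical name -> character vector of aliases.
#' @export
default_structure_aliases <- function() {
  list(body = c("body", "external", "skin", "outer contour"),
       TLV = c("tlv", "liver", "total liver volume", "whole liver"),
       PGTV = c("pgtv", "gtv", "ptv", "tumor", "tumour"),
       duodenum = "duodenum",
       stomach = c("stomach", "gaster"),
       esophagus = c("esophagus", "oesophagus"),
       heart = "heart",
       spleen = "spleen")
}

match_structure_names <- function(roi_names, aliases) {
  canon <- canonical_structures()
  lut <- character(0)
  for (nm in canon)
    for (a in unique(c(tolower(nm), tolower(aliases[[nm]]))))
      lut[a] <- nm
  out <- rep(NA_character_, length(roi_names))
  hit <- tolower(trimws(roi_names)) %in% names(lut)
  out[hit] <- lut[tolower(trimws(roi_names))[hit]]
  out
}

ct_slice_dataset <- function(case, k, uids) {
  g <- case$volume
  ipp <- c(g$origin[1] + g$spacing[1] / 2,
           g$origin[2] + g$spacing[2] / 2,
           g$origin[3] + (k - 0.5) * g$spacing[3])
  sop <- new_uid()
  ds <- list()
  ds[[tag_key(0x0008, 0x0016)]] <- dcm_el("UI", UID_CT)
  ds[[tag_key(0x0008, 0x0018)]] <- dcm_el("UI", sop)
  ds[[tag_key(0x0008, 0x0060)]] <- dcm_el("CS", "CT")
  ds[[tag_key(0x0010, 0x0020)]] <- dcm_el("LO", case$case_id)
  ds[[tag_key(0x0020, 0x000D)]] <- dcm_el("UI", uids$study)
  ds[[tag_key(0x0020, 0x000E)]] <- dcm_el("UI", uids$ct_series)
  ds[[tag_key(0x0020, 0x0013)]] <- dcm_el("IS", as.character(k))
  ds[[tag_key(0x0020, 0x0032)]] <- dcm_el("DS", ds_str(ipp))
  ds[[tag_key(0x0020, 0x0037)]] <- dcm_el("DS", c("1", "0", "0", "0", "1", "0"))
  ds[[tag_key(0x0028, 0x0002)]] <- dcm_el("US", 1L)
  ds[[tag_key(0x0028, 0x0004)]] <- dcm_el("CS", "MONOCHROME2")
  ds[[tag_key(0x0028, 0x0010)]] <- dcm_el("US", g$shape[2])  # rows (y)
  ds[[tag_key(0x0028, 0x0011)]] <- dcm_el("US", g$shape[1])  # cols (x)
  ds[[tag_key(0x0028, 0x0030)]] <- dcm_el("DS", ds_str(g$spacing[c(2, 1)]))
  ds[[tag_key(0x0018, 0x0050)]] <- dcm_el("DS", ds_str(g$spacing[3]))
  ds[[tag_key(0x0028, 0x0100)]] <- dcm_el("US", 16L)
  ds[[tag_key(0x0028, 0x0101)]] <- dcm_el("US", 16L)
  ds[[tag_key(0x0028, 0x0102)]] <- dcm_el("US", 15L)
  ds[[tag_key(0x0028, 0x0103)]] <- dcm_el("US", 1L)  # signed
  ds[[tag_key(0x0028, 0x1052)]] <- dcm_el("DS", "0")
  ds[[tag_key(0x0028, 0x1053)]] <- dcm_el("DS", "1")
  ds[[tag_key(0x7FE0, 0x0010)]] <-
    dcm_el("OW", int16_raw(as.vector(case$volume$voxels[, , k])))
  list(ds = ds, sop = sop)
}

#' Write a case as a DICOM CT series + RTSTRUCT + RTPLAN
#'
#' Emits one CT file per slice (`ct_####.dcm`), a structure set with the
#' eight canonical structures (voxel-edge contours, so re-reading
#' reproduces the masks exactly), and a plan with one beam per clinical
#' gantry angle, all re-readable by [read_case()].
#'
#' @param case a [patient_case()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  uids <- list(study = new_uid(), ct_series = new_uid())
  for (k in seq_len(case$volume$shape[3])) {
    sl <- ct_slice_dataset(case, k, uids)
    dcm_write_file(file.path(path, sprintf("ct_%04d.dcm", k)), sl$ds,
                   UID_CT, sl$sop)
  }
  # RTSTRUCT
  roi_items <- list()
  contour_items <- list()
  for (ri in seq_along(case$structures)) {
    nm <- names(case$structures)[ri]
    roi <- list()
    roi[[tag_key(0x3006, 0x0022)]] <- dcm_el("IS", as.character(ri))
    roi[[tag_key(0x3006, 0x0026)]] <- dcm_el("LO", nm)
    roi_items[[ri]] <- roi
    cts <- mask_to_contours(case$structures[[nm]], case$volume)
    citems <- lapply(cts, function(p) {
      it <- list()
      it[[tag_key(0x3006, 0x0042)]] <- dcm_el("CS", "CLOSED_PLANAR")
      it[[tag_key(0x3006, 0x0046)]] <- dcm_el("IS", as.character(nrow(p)))
      it[[tag_key(0x3006, 0x0050)]] <- dcm_el("DS", ds_str(as.vector(t(p))))
      it
    })
    ci <- list()
    ci[[tag_key(0x3006, 0x0084)]] <- dcm_el("IS", as.character(ri))
    if (length(citems))
      ci[[tag_key(0x3006, 0x0040)]] <- dcm_el("SQ", citems)
    contour_items[[ri]] <- ci
  }
  rs <- list()
  rs_sop <- new_uid()
  rs[[tag_key(0x0008, 0x0016)]] <- dcm_el("UI", UID_RTSTRUCT)
  rs[[tag_key(0x0008, 0x0018)]] <- dcm_el("UI", rs_sop)
  rs[[tag_key(0x0008, 0x0060)]] <- dcm_el("CS", "RTSTRUCT")
  rs[[tag_key(0x0010, 0x0020)]] <- dcm_el("LO", case$case_id)
  rs[[tag_key(0x0020, 0x000D)]] <- dcm_el("UI", uids$study)
  rs[[tag_key(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  rs[[tag_key(0x3006, 0x0020)]] <- dcm_el("SQ", roi_items)
  rs[[tag_key(0x3006, 0x0039)]] <- dcm_el("SQ", contour_items)
  dcm_write_file(file.path(path, "rtstruct.dcm"), rs, UID_RTSTRUCT, rs_sop)
  # RTPLAN
  beams <- lapply(seq_along(case$clinical_angles), function(bi) {
    cp <- list()
    cp[[tag_key(0x300A, 0x0112)]] <- dcm_el("IS", "0")
    cp[[tag_key(0x300A, 0x011E)]] <- dcm_el("DS",
                                            ds_str(case$clinical_angles[bi]))
    cp[[tag_key(0x300A, 0x012C)]] <- dcm_el("DS", ds_str(case$isocenter))
    b <- list()
    b[[tag_key(0x300A, 0x00C0)]] <- dcm_el("IS", as.character(bi))
    b[[tag_key(0x300A, 0x0111)]] <- dcm_el("SQ", list(cp))
    b
  })
  rp <- list()
  rp_sop <- new_uid()
  rp[[tag_key(0x0008, 0x0016)]] <- dcm_el("UI", UID_RTPLAN)
  rp[[tag_key(0x0008, 0x0018)]] <- dcm_el("UI", rp_sop)
  rp[[tag_key(0x0008, 0x0060)]] <- dcm_el("CS", "RTPLAN")
  rp[[tag_key(0x0010, 0x0020)]] <- dcm_el("LO", case$case_id)
  rp[[tag_key(0x0020, 0x000D)]] <- dcm_el("UI", uids$study)
  rp[[tag_key(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  if (length(beams))
    rp[[tag_key(0x300A, 0x00B0)]] <- dcm_el("SQ", beams)
  dcm_write_file(file.path(path, "rtplan.dcm"), rp, UID_RTPLAN, rp_sop)
  invisible(path)
}

#' Read a case from DICOM CT series + RTSTRUCT + RTPLAN
#'
#' Slices are sorted by z position and must be uniformly spaced; contours
#' are matched to the eight canonical structure names through the
#' (case-insensitive) alias table and rasterized onto the CT grid with
#' even-odd fill; gantry angles come from each beam's first control point
#' and the isocenter from the first beam.
#'
#' @param ct_path directory containing the CT slice files (`*.dcm`; other
#'   modalities in the directory are ignored).
#' @param rtstruct_path the RTSTRUCT file.
#' @param rtplan_path the RTPLAN file.
#' @param aliases structure-name alias table
#'   (default [default_structure_aliases()]).
#' @return a [patient_case()].
#' @export
read_case <- function(ct_path, rtstruct_path, rtplan_path,
                      aliases = default_structure_aliases()) {
  files <- list.files(ct_path, pattern = "\\.dcm$", full.names = TRUE)
  slices <- list()
  for (f in files) {
    ds <- dcm_read_file(f)
    if (identical(dcm_get(ds, 0x0008, 0x0016), UID_CT))
      slices[[length(slices) + 1L]] <- ds
  }
  if (!length(slices)) stop("no CT slices found in ", ct_path)
  zs <- vapply(slices, function(ds) dcm_get(ds, 0x0020, 0x0032)[3],
               numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (max(dz) - min(dz) > 1e-3)
      stop("non-uniform CT slice spacing; measured spacings: ",
           paste(sprintf("%.4f", unique(round(dz, 4))), collapse = ", "))
    dz <- stats::median(dz)
  } else dz <- dcm_get(slices[[1]], 0x0018, 0x0050, 1)
  s1 <- slices[[1]]
  nrow_px <- dcm_get(s1, 0x0028, 0x0010)
  ncol_px <- dcm_get(s1, 0x0028, 0x0011)
  psp <- dcm_get(s1, 0x0028, 0x0030)  # (row, col)
  ipp <- dcm_get(s1, 0x0020, 0x0032)
  spacing <- c(psp[2], psp[1], dz)
  origin <- c(ipp[1] - spacing[1] / 2, ipp[2] - spacing[2] / 2,
              zs[1] - spacing[3] / 2)
  slope <- dcm_get(s1, 0x0028, 0x1053, 1)
  intercept <- dcm_get(s1, 0x0028, 0x1052, 0)
  vox <- array(0, c(ncol_px, nrow_px, length(slices)))
  for (k in seq_along(slices)) {
    pr <- dcm_get(slices[[k]], 0x7FE0, 0x0010)
    v <- readBin(pr, "integer", n = ncol_px * nrow_px, size = 2,
                 signed = TRUE, endian = "little")
    vox[, , k] <- v * slope + intercept
  }
  grid <- volume_grid(vox, spacing, origin)

  rs <- dcm_read_file(rtstruct_path)
  rois <- dcm_get(rs, 0x3006, 0x0020)
  roi_names <- vapply(rois, function(it) dcm_get(it, 0x3006, 0x0026),
                      character(1))
  roi_nums <- vapply(rois, function(it) dcm_get(it, 0x3006, 0x0022),
                     numeric(1))
  canon <- match_structure_names(roi_names, aliases)
  missing <- setdiff(canonical_structures(), canon)
  if (length(missing))
    stop("RTSTRUCT is missing canonical structure(s): ",
         paste(missing, collapse = ", "))
  contour_seq <- dcm_get(rs, 0x3006, 0x0039)
  masks <- list()
  for (ci in contour_seq) {
    num <- dcm_get(ci, 0x3006, 0x0084)
    nm <- canon[match(num, roi_nums)]
    if (is.na(nm)) next
    items <- dcm_get(ci, 0x3006, 0x0040, list())
    polys <- lapply(items, function(it)
      matrix(dcm_get(it, 0x3006, 0x0050), ncol = 3, byrow = TRUE))
    masks[[nm]] <- contours_to_mask(polys, grid)
  }
  ss <- structure_set(masks, grid)

  rp <- dcm_read_file(rtplan_path)
  beams <- dcm_get(rp, 0x300A, 0x00B0, list())
  angles <- numeric(0)
  iso <- NULL
  for (b in beams) {
    cps <- dcm_get(b, 0x300A, 0x0111, list())
    if (!length(cps)) next
    angles <- c(angles, dcm_get(cps[[1]], 0x300A, 0x011E))
    if (is.null(iso)) iso <- dcm_get(cps[[1]], 0x300A, 0x012C)
  }
  if (is.null(iso)) {
    idx <- which(ss$PGTV == 1L, arr.ind = TRUE)
    ax <- grid_axes(grid)
    iso <- sapply(1:3, function(a) mean(ax[[a]][idx[, a]]))
  }
  patient_case(dcm_get(s1, 0x0010, 0x0020, "case"), grid, ss, iso,
               angles %% 360)
}

#' Write a dose grid as a multiframe DICOM RTDOSE
#'
#' Stored as 16-bit unsigned pixels with a fixed dose-grid scaling of 1/64
#' (% per pixel unit) when the maximum dose allows, so integer and
#' 1/64-step dose values round-trip exactly.
#'
#' @param dose a [dose_grid()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_dose <- function(dose, path) {
  g <- dose$grid
  mx <- max(dose$dose)
  scaling <- if (mx <= 65535 / 64) 1 / 64 else mx / 65535
  px <- round(dose$dose / scaling)
  ipp <- c(g$origin[1] + g$spacing[1] / 2, g$origin[2] + g$spacing[2] / 2,
           g$origin[3] + g$spacing[3] / 2)
  sop <- new_uid()
  ds <- list()
  ds[[tag_key(0x0008, 0x0016)]] <- dcm_el("UI", UID_RTDOSE)
  ds[[tag_key(0x0008, 0x0018)]] <- dcm_el("UI", sop)
  ds[[tag_key(0x0008, 0x0060)]] <- dcm_el("CS", "RTDOSE")
  ds[[tag_key(0x0020, 0x000D)]] <- dcm_el("UI", new_uid())
  ds[[tag_key(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  ds[[tag_key(0x0020, 0x0032)]] <- dcm_el("DS", ds_str(ipp))
  ds[[tag_key(0x0020, 0x0037)]] <- dcm_el("DS", c("1", "0", "0", "0", "1", "0"))
  ds[[tag_key(0x0028, 0x0002)]] <- dcm_el("US", 1L)
  ds[[tag_key(0x0028, 0x0004)]] <- dcm_el("CS", "MONOCHROME2")
  ds[[tag_key(0x0028, 0x0008)]] <- dcm_el("IS", as.character(g$shape[3]))
  ds[[tag_key(0x0028, 0x0010)]] <- dcm_el("US", g$shape[2])
  ds[[tag_key(0x0028, 0x0011)]] <- dcm_el("US", g$shape[1])
  ds[[tag_key(0x0028, 0x0030)]] <- dcm_el("DS", ds_str(g$spacing[c(2, 1)]))
  ds[[tag_key(0x0028, 0x0100)]] <- dcm_el("US", 16L)
  ds[[tag_key(0x0028, 0x0101)]] <- dcm_el("US", 16L)
  ds[[tag_key(0x0028, 0x0102)]] <- dcm_el("US", 15L)
  ds[[tag_key(0x0028, 0x0103)]] <- dcm_el("US", 0L)  # unsigned
  ds[[tag_key(0x3004, 0x0002)]] <- dcm_el("CS", "RELATIVE")
  ds[[tag_key(0x3004, 0x000C)]] <-
    dcm_el("DS", ds_str((seq_len(g$shape[3]) - 1L) * g$spacing[3]))
  ds[[tag_key(0x3004, 0x000E)]] <- dcm_el("DS", sprintf("%.12g", scaling))
  ds[[tag_key(0x7FE0, 0x0010)]] <- dcm_el("OW", u16_raw(as.vector(px)))
  dcm_write_file(path, ds, UID_RTDOSE, sop)
  invisible(path)
}

#' Read a DICOM RTDOSE and resample it onto a reference grid
#'
#' Dose values are returned in % of prescription (the stored values times
#' the dose-grid scaling). If the dose grid geometry matches the reference
#' exactly the array passes through untouched; otherwise it is resampled
#' trilinearly at the reference voxel centers (0 outside the dose grid).
#' Grids that do not overlap at all raise an error.
#'
#' @param rtdose_path the RTDOSE file.
#' @param reference the reference [volume_grid()].
#' @param prescription_level % isodose level stored on the result
#'   (default 100).
#' @return a [dose_grid()] on the reference grid.
#' @export
read_dose <- function(rtdose_path, reference, prescription_level = 100) {
  ds <- dcm_read_file(rtdose_path)
  if (!identical(dcm_get(ds, 0x0008, 0x0016), UID_RTDOSE))
    stop("not an RTDOSE file: ", rtdose_path)
  nrow_px <- dcm_get(ds, 0x0028, 0x0010)
  ncol_px <- dcm_get(ds, 0x0028, 0x0011)
  nfr <- as.integer(dcm_get(ds, 0x0028, 0x0008))
  psp <- dcm_get(ds, 0x0028, 0x0030)
  ipp <- dcm_get(ds, 0x0020, 0x0032)
  offs <- dcm_get(ds, 0x3004, 0x000C)
  scaling <- dcm_get(ds, 0x3004, 0x000E)
  pr <- dcm_get(ds, 0x7FE0, 0x0010)
  px <- readBin(pr, "integer", n = ncol_px * nrow_px * nfr, size = 2,
                signed = FALSE, endian = "little")
  dz <- if (nfr > 1) stats::median(diff(offs)) else reference$spacing[3]
  spacing <- c(psp[2], psp[1], dz)
  origin <- c(ipp[1] - spacing[1] / 2, ipp[2] - spacing[2] / 2,
              ipp[3] + offs[1] - spacing[3] / 2)
  dvol <- volume_grid(array(px * scaling, c(ncol_px, nrow_px, nfr)),
                      spacing, origin)
  same <- identical(dvol$shape, reference$shape) &&
    max(abs(dvol$spacing - reference$spacing)) < 1e-6 &&
    max(abs(dvol$origin - reference$origin)) < 1e-6
  if (same)
    return(dose_grid(dvol$voxels, reference,
                     prescription_level = prescription_level))
  # overlap check on bounding boxes
  lo_d <- dvol$origin; hi_d <- dvol$origin + dvol$shape * dvol$spacing
  lo_r <- reference$origin
  hi_r <- reference$origin + reference$shape * reference$spacing
  if (any(hi_d <= lo_r) || any(lo_d >= hi_r))
    stop("dose grid does not overlap the reference grid")
  ax <- grid_axes(reference)
  nx <- reference$shape[1]; ny <- reference$shape[2]; nz <- reference$shape[3]
  pts <- cbind(rep(ax[[1]], times = ny * nz),
               rep(rep(ax[[2]], each = nx), times = nz),
               rep(ax[[3]], each = nx * ny))
  vals <- sample_trilinear(dvol, pts, outside = 0)
  vals[vals < 0] <- 0
  dose_grid(array(vals, reference$shape), reference,
            prescription_level = prescription_level)
}
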