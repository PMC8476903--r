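# Internal case container: a directory of raw little-endian arrays plus a
# JSON sidecar carrying the grid metadata, structure order and angles.

write_array_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_array_bin <- function(path, dim) {
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "double", n = prod(dim), size = 8,
                endian = "little"), dim = dim)
}

#' Write a case to the internal container format
#'
#' A directory with `case.json` (grid metadata, structure order, isocenter,
#' angles) plus one little-endian double array per volume and mask.
#'
#' @param case a [patient_case()].
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_case_dir <- function(case, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(case_id = case$case_id,
               shape = case$volume$shape,
               spacing = case$volume$spacing,
               origin = case$volume$origin,
               isocenter = case$isocenter,
               clinical_angles = case$clinical_angles,
               structures = names(case$structures))
  jsonlite::write_json(meta, file.path(path, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_bin(case$volume$voxels, file.path(path, "volume.bin"))
  for (nm in names(case$structures))
    write_array_bin(case$structures[[nm]],
                    file.path(path, paste0("mask_", nm, ".bin")))
  invisible(path)
}

#' Read a case from the internal container format
#'
#' @param path directory written by [write_case_dir()].
#' @return a [patient_case()].
#' @export
read_case_dir <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "case.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  grid <- volume_grid(read_array_bin(file.path(path, "volume.bin"), shape),
                      meta$spacing, meta$origin)
  masks <- lapply(meta$structures, function(nm)
    read_array_bin(file.path(path, paste0("mask_", nm, ".bin")), shape))
  names(masks) <- meta$structures
  patient_case(meta$case_id, grid, structure_set(masks, grid),
               meta$isocenter,
               if (is.null(meta$clinical_angles)) numeric(0)
               else as.numeric(meta$clinical_angles))
}

#' Write / read a feature tensor
#'
#' Binary array container: `header.json` plus a little-endian double array.
#'
#' @param ft a `baods_features` object.
#' @param path directory (created if absent).
#' @return `path` invisibly (write); the `baods_features` (read).
#' @export
write_features <- function(ft, path) {
  stopifnot(inherits(ft, "baods_features"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(case_id = ft$case_id, angles = ft$angles,
               n_rays = ft$n_rays, n_features = ft$n_features,
               n_bins = ft$n_bins, n_rows = nrow(ft$values),
               layout = "row = angle*225 + ray*9 + feature (0-based)")
  jsonlite::write_json(meta, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_bin(ft$values, file.path(path, "values.bin"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "header.json"),
                              simplifyVector = TRUE)
  vals <- read_array_bin(file.path(path, "values.bin"),
                         c(meta$n_rows, meta$n_bins))
  structure(list(values = vals, angles = as.numeric(meta$angles),
                 case_id = meta$case_id, n_rays = as.integer(meta$n_rays),
                 n_features = as.integer(meta$n_features),
                 n_bins = as.integer(meta$n_bins)),
            class = "baods_features")
}

#' Write / read a ranking score vector as plain text
#'
#' One value per line, 360 lines, angles 0..359.
#'
#' @param sbeam numeric vector of length 360.
#' @param path file path.
#' @return `path` invisibly (write); numeric vector of length 360 (read).
#' @export
write_sbeam <- function(sbeam, path) {
  stopifnot(length(sbeam) == 360)
  writeLines(sprintf("%.17g", sbeam), path)
  invisible(path)
}

#' @rdname write_sbeam
#' @export
read_sbeam <- function(path) {
  v <- as.numeric(readLines(path))
  if (length(v) != 360) stop("expected 360 lines, got ", length(v))
  v
}

#' Save / load a network (parameters, running statistics, spec)
#'
#' @param net a `baods_net`.
#' @param path file path (.rds).
#' @return `path` invisibly (save); the `baods_net` (load).
#' @export
save_net <- function(net, path) {
  stopifnot(inherits(net, "baods_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "baods_net")) stop("file does not contain a baods_net")
  net
}
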