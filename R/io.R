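#' Construct an activity volume
#'
#' The basic container: a 3-D nonnegative array of activity concentration
#' (kBq/ml) plus its voxel spacing in mm.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm Voxel edge lengths in mm (length 3).
#' @return An `activity_volume` object.
#' @export
activity_volume <- function(data, spacing_mm) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < 0, na.rm = TRUE)) stop("activity must be nonnegative")
  voxel_volume_ml(spacing_mm)
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "activity_volume: %d x %d x %d voxels, spacing %g x %g x %g mm (%.3g ml/voxel)\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    voxel_volume_ml(x$spacing_mm)))
  cat(sprintf("  range [%.4g, %.4g] kBq/ml\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Read a PET volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [activity_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("volume has no usable voxel spacing in its header")
  activity_volume(array(as.numeric(img), dim(img)[1:3]), sp)
}

#' Write a volume (or label field) as NIfTI-1
#'
#' @param vol An [activity_volume()], or a plain 3-D array (then
#'   `spacing_mm` is required). Data are stored as float64 so round trips
#'   are bit-exact.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing_mm Spacing when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = NULL) {
  if (inherits(vol, "activity_volume")) {
    data <- vol$data; spacing_mm <- vol$spacing_mm
  } else {
    stopifnot(is.array(vol), !is.null(spacing_mm))
    data <- vol
  }
  img <- RNifti::asNifti(structure(data + 0.0, pixdim = spacing_mm),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Axis-aligned VOI box (0-based, half-open)
#'
#' `start` is inclusive, `end` exclusive, per axis; the voxel count is
#' `prod(end - start)`.
#'
#' @param start,end Integer triples of voxel indices.
#' @return A `voi_box` object.
#' @export
voi_box <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 3, length(end) == 3)
  if (any(start < 0) || any(end <= start))
    stop("invalid VOI box: require 0 <= start < end per axis")
  structure(list(start = start, end = end, shape = end - start),
            class = "voi_box")
}

#' @export
print.voi_box <- function(x, ...) {
  cat(sprintf("voi_box: [%d:%d, %d:%d, %d:%d) = %d voxels\n",
              x$start[1], x$end[1], x$start[2], x$end[2],
              x$start[3], x$end[3], prod(x$shape)))
  invisible(x)
}

#' Centered VOI box of a given voxel shape
#'
#' Builds a box of `shape` voxels centered (up to integer rounding) on a
#' physical point, clipped to the grid.
#'
#' @param center_mm Physical center in mm.
#' @param shape Voxel counts per axis, e.g. `c(14, 14, 20)`.
#' @param grid_shape Full grid voxel counts.
#' @param spacing_mm Voxel spacing in mm.
#' @export
voi_box_around <- function(center_mm, shape, grid_shape, spacing_mm) {
  shape <- as.integer(shape)
  ci <- floor(center_mm / spacing_mm)        # 0-based voxel holding center
  start <- pmax(0L, pmin(as.integer(ci - shape %/% 2L),
                         as.integer(grid_shape - shape)))
  voi_box(start, start + shape)
}

#' Extract the VOI values from a volume
#'
#' @param vol An [activity_volume()] or a 3-D array.
#' @param box A [voi_box()].
#' @return A 3-D array of `box$shape`, with the box kept as attribute
#'   `"voi_box"` so labels can be written back with [insert_voi()].
#' @export
extract_voi <- function(vol, box) {
  data <- if (inherits(vol, "activity_volume")) vol$data else vol
  stopifnot(inherits(box, "voi_box"))
  if (any(box$end > dim(data))) stop("VOI box out of bounds")
  idx <- lapply(1:3, function(a) (box$start[a] + 1):box$end[a])
  out <- data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  attr(out, "voi_box") <- box
  out
}

#' Write VOI-shaped values back into a full-grid array
#'
#' @param full 3-D array (modified copy is returned).
#' @param values Array of the box's shape.
#' @param box A [voi_box()]; defaults to the `"voi_box"` attribute of
#'   `values`.
#' @export
insert_voi <- function(full, values, box = attr(values, "voi_box")) {
  stopifnot(inherits(box, "voi_box"), all(dim(values) == box$shape))
  idx <- lapply(1:3, function(a) (box$start[a] + 1):box$end[a])
  full[idx[[1]], idx[[2]], idx[[3]]] <- values
  full
}

#' Parse a CLI VOI string `x0:x1,y0:y1,z0:z1` (0-based half-open)
#' @param text The string.
#' @export
parse_voi <- function(text) {
  parts <- strsplit(strsplit(text, ",")[[1]], ":")
  if (length(parts) != 3 || any(lengths(parts) != 2))
    stop("VOI must be 'x0:x1,y0:y1,z0:z1'")
  m <- vapply(parts, as.integer, integer(2))
  voi_box(m[1, ], m[2, ])
}
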