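# Condition helpers ---------------------------------------------------------

ctr_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ctr_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

geometry_error  <- function(msg) ctr_error(msg, "ctr_geometry_error")
format_error    <- function(msg) ctr_error(msg, "ctr_format_error")
lookup_error    <- function(msg) ctr_error(msg, "ctr_lookup_error")
empty_roi_error <- function(msg) ctr_error(msg, "ctr_empty_roi_error")
parameter_error <- function(msg) ctr_error(msg, "ctr_parameter_error")
schema_error    <- function(msg) ctr_error(msg, "ctr_schema_error")
config_error    <- function(msg) ctr_error(msg, "ctr_config_error")
extraction_error <- function(msg) ctr_error(msg, "ctr_extraction_error")

# VoxelVolume ---------------------------------------------------------------

#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3-D scalar grid with physical geometry: voxel
#' spacing along (x, y, z) in millimetres and the physical coordinate of
#' voxel (1,1,1). For CT data the values are Hounsfield units. Array axes
#' are ordered (x, y, z); the physical position of voxel index
#' `(i, j, k)` (1-based) is `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3, voxel size in mm; all components > 0.
#' @param origin numeric length-3, physical coordinate (mm) of the first
#'   voxel centre.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    geometry_error("`data` must be a 3-D array")
  if (any(dim(data) < 1L))
    geometry_error("every volume dimension must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    geometry_error("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    geometry_error("`origin` must be 3 finite numbers")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 6), collapse = ", "),
      ") mm, origin (", paste(signif(x$origin, 6), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Construct a segmentation mask
#'
#' A binary voxel grid aligned to a [voxel_volume()]; in tumor studies this
#' is the clinician-delineated gross tumor volume (GTV).
#'
#' @param data logical (or coercible) 3-D array.
#' @inheritParams voxel_volume
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    geometry_error("mask `data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    geometry_error("`spacing` must be 3 positive numbers")
  m <- array(as.logical(data != 0), dim = dim(data))
  structure(list(data = m, spacing = spacing, origin = origin),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " in mask\n", sep = "")
  invisible(x)
}

#' @export
dim.segmentation_mask <- function(x) dim(x$data)

# geometry alignment check used throughout extraction
check_aligned <- function(volume, mask, tol = 1e-3) {
  if (!identical(dim(volume$data), dim(mask$data)))
    geometry_error("volume and mask grids have different shapes")
  if (max(abs(volume$spacing - mask$spacing)) > tol ||
      max(abs(volume$origin - mask$origin)) > tol)
    geometry_error("volume and mask geometry differ beyond tolerance")
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (!any(mask$data))
    empty_roi_error("segmentation mask contains no voxels")
  invisible(TRUE)
}

# ContourSet ----------------------------------------------------------------

#' Construct a contour set
#'
#' Planar closed polygons, as stored in DICOM-RTSTRUCT: each contour lies
#' on one axial plane (constant z) and is described by ordered (x, y)
#' vertices in physical millimetres, grouped under a region-of-interest
#' name.
#'
#' @param contours a list; each element a list with fields `roi` (name),
#'   `z` (slice position, mm) and `vertices` (n x 2 matrix of x, y in mm,
#'   n >= 3).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(contours) {
  for (ct in contours) {
    if (is.null(ct$roi) || is.null(ct$z) || is.null(ct$vertices))
      format_error("each contour needs `roi`, `z` and `vertices`")
    v <- ct$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      format_error("contour vertices must be an n x 2 matrix with n >= 3")
  }
  structure(list(contours = contours), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  rois <- vapply(x$contours, function(ct) ct$roi, character(1))
  cat("<contour_set> ", length(x$contours), " contours, ROIs: ",
      paste(unique(rois), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' ROI names present in a contour set
#' @param contours a [contour_set()].
#' @return character vector of unique ROI names.
#' @export
contour_roi_names <- function(contours) {
  unique(vapply(contours$contours, function(ct) ct$roi, character(1)))
}
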