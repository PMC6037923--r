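# Contour-to-mask rasterization. A voxel belongs to the mask iff its centre
# lies inside the slice polygon under the even-odd (parity) rule, applied
# half-open in the standard scanline fashion: a centre on the left/bottom
# boundary is inside, on the right/top boundary outside. The tie-break is
# deterministic and adjacency-safe (two abutting contours never claim the
# same centre twice). Polygons on the same slice combine by parity, so
# ring-shaped structures (holes) work.

# Even-odd point-in-polygon for many points at once.
# px, py: point coordinates; vx, vy: polygon vertices (closed implicitly).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # edge-crossing parity for a ray toward +x
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a reference grid
#'
#' Converts the closed polygons of one region of interest into a binary
#' mask on the grid of `reference`. A voxel is inside when its centre
#' satisfies the even-odd rule for the polygon(s) of its slice; centres on
#' an edge count as inside. Each contour is assigned to the slice whose
#' z-position is nearest, and must lie within half a slice spacing of it.
#'
#' @param contours a [contour_set()], e.g. from [read_rtstruct()].
#' @param reference the [voxel_volume()] defining the output grid.
#' @param roi_name which ROI to rasterize.
#' @return A [segmentation_mask()] aligned to `reference`.
#' @export
rasterize_contours <- function(contours, reference, roi_name) {
  sel <- Filter(function(ct) ct$roi == roi_name, contours$contours)
  if (length(sel) == 0L)
    lookup_error(sprintf("ROI '%s' not present in contour set", roi_name))
  dims <- dim(reference$data)
  sp <- reference$spacing; or <- reference$origin
  zs <- or[3] + (seq_len(dims[3]) - 1) * sp[3]
  xc <- or[1] + (seq_len(dims[1]) - 1) * sp[1]
  yc <- or[2] + (seq_len(dims[2]) - 1) * sp[2]
  mask <- array(FALSE, dim = dims)
  half_dz <- sp[3] / 2 + 1e-6
  px <- rep(xc, times = dims[2])
  py <- rep(yc, each = dims[1])
  for (ct in sel) {
    k <- which.min(abs(zs - ct$z))
    if (abs(zs[k] - ct$z) > half_dz)
      geometry_error(sprintf(
        "contour at z = %.3f mm matches no slice of the reference grid", ct$z))
    inside <- points_in_polygon(px, py, ct$vertices[, 1], ct$vertices[, 2])
    mask[, , k] <- xor(mask[, , k], matrix(inside, nrow = dims[1]))
  }
  segmentation_mask(mask, spacing = sp, origin = or)
}
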