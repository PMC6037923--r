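# Intensity extraction and fixed-bin-width gray-level discretization.
# Bins are anchored at the masked minimum, so the coding is invariant to
# adding a constant to all intensities; width defaults to 25 HU.

#' Extract masked voxel intensities
#'
#' Returns the intensities of all mask voxels in raster order (x fastest,
#' then y, then z — R's native array order).
#'
#' @param volume a [voxel_volume()].
#' @param mask a [segmentation_mask()] aligned to `volume`.
#' @return numeric vector of intensities, one per mask voxel.
#' @export
extract_masked_intensities <- function(volume, mask) {
  check_aligned(volume, mask)
  check_nonempty(mask)
  as.numeric(volume$data[mask$data])
}

#' Discretize a masked region into gray levels
#'
#' Re-codes masked intensities to integer levels with equally spaced bins of
#' width `bin_width`, anchored at the masked minimum:
#' `level(x) = floor((x - min) / bin_width) + 1`. Voxels outside the mask
#' get level 0. The number of levels is
#' `G = floor((max - min) / bin_width) + 1`; the maximum always falls in
#' bin G (no clipping).
#'
#' @param volume a [voxel_volume()] (or any object with `$data` a 3-D array).
#' @param mask a [segmentation_mask()] aligned to `volume`.
#' @param bin_width bin width, in Hounsfield units for CT (default 25).
#' @return An object of class `discretized_roi` with fields `grid` (integer
#'   3-D array), `n_levels`, `bin_width`, `bin_origin` (the masked minimum)
#'   and `mask` (logical array).
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    parameter_error("`bin_width` must be a positive number")
  check_aligned(volume, mask)
  check_nonempty(mask)
  vals <- volume$data[mask$data]
  lo <- min(vals)
  grid <- array(0L, dim = dim(volume$data))
  grid[mask$data] <- as.integer(floor((vals - lo) / bin_width)) + 1L
  g <- max(grid)
  structure(list(grid = grid, n_levels = g, bin_width = bin_width,
                 bin_origin = lo, mask = mask$data),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat("<discretized_roi> ", sum(x$mask), " voxels, ", x$n_levels,
      " gray levels (bin width ", x$bin_width, ")\n", sep = "")
  invisible(x)
}

# histogram probabilities over fixed-width bins anchored at min(values)
bin_probabilities <- function(values, bin_width) {
  lev <- floor((values - min(values)) / bin_width) + 1
  counts <- tabulate(lev, nbins = max(lev))
  counts[counts > 0] / length(values)
}
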