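# One-level undecimated (stationary) 3-D wavelet decomposition. The volume
# is separably correlated with a low-pass (L) or high-pass (H) analysis
# filter along each axis, with no downsampling, giving 8 sub-bands named by
# their filter pattern: the first subscript letter filters the x-axis, the
# second y, the third z (X_HLH = high-pass in x, low-pass in y, high-pass
# in z). Filters are placed by the centred-correlation convention of
# `correlate_axis()`, so results are bit-reproducible.

WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

# orthonormal analysis filter banks (decomposition low/high pass)
WAVELET_FILTERS <- list(
  haar = list(
    L = c(0.7071067811865476, 0.7071067811865476),
    H = c(-0.7071067811865476, 0.7071067811865476)),
  coif1 = list(
    L = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    H = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)))

#' Analysis filter pair of a wavelet family
#'
#' @param family `"coif1"` (default) or `"haar"`.
#' @return list with components `L` (low pass), `H` (high pass; sums to 0)
#'   and `family`.
#' @export
wavelet_filters <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  f <- WAVELET_FILTERS[[family]]
  c(f, list(family = family))
}

#' One-level undecimated 3-D wavelet decomposition
#'
#' Decomposes a volume into its 8 stationary wavelet sub-bands
#' (LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH), each the same shape as the
#' input. Subscript letters name the axis filters in (x, y, z) order.
#'
#' @param volume a [voxel_volume()].
#' @param filters a filter pair from [wavelet_filters()].
#' @param boundary extension mode: `"symmetric"` (default), `"periodic"`
#'   or `"zero"`.
#' @return named list of 8 [voxel_volume()] objects, one per sub-band.
#' @export
undecimated_wavelet_3d <- function(volume, filters = wavelet_filters(),
                                   boundary = "symmetric") {
  if (is.null(filters$L) || is.null(filters$H) ||
      length(filters$L) < 2L || length(filters$H) < 2L)
    parameter_error("filters must supply low- and high-pass taps (length >= 2)")
  if (abs(sum(filters$H)) > 1e-9)
    parameter_error("high-pass filter taps must sum to zero")
  x <- volume$data
  # cascade axis by axis: 2 -> 4 -> 8 partial products
  bands <- stats::setNames(list(x), "")
  for (axis in 1:3) {
    nxt <- list()
    for (bi in seq_along(bands)) {
      nm <- names(bands)[bi]
      nxt[[paste0(nm, "L")]] <- correlate_axis(bands[[bi]], filters$L, axis, boundary)
      nxt[[paste0(nm, "H")]] <- correlate_axis(bands[[bi]], filters$H, axis, boundary)
    }
    bands <- nxt
  }
  out <- lapply(WAVELET_BANDS, function(b) {
    # name order is (x, y, z); the cascade above appended x first
    voxel_volume(bands[[b]], spacing = volume$spacing, origin = volume$origin)
  })
  names(out) <- WAVELET_BANDS
  out
}

#' Wavelet-domain feature block
#'
#' Runs the one-level undecimated decomposition and computes the 14
#' first-order and 33 texture features on every sub-band, restricted to the
#' same mask as the original image: 8 x 47 = 376 features named
#' `<BAND>_<Feature>` (e.g. `HLH_Median`, `LLL_Energy`).
#'
#' Sub-band voxel values are not Hounsfield units, so the fixed 25-HU bin
#' width does not transfer; each sub-band is discretized with its own
#' min-anchored bins per `bin_policy`:
#' `"match_level_count"` (default) chooses the width so the sub-band gets
#' the same number of gray levels as the original image;
#' `"fixed_width"` reuses `bin_width` unchanged.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [segmentation_mask()] aligned to `volume`.
#' @param filters a filter pair from [wavelet_filters()].
#' @param bin_policy sub-band discretization policy (see above).
#' @param bin_width original-image bin width in HU (default 25).
#' @param boundary wavelet boundary mode (default `"symmetric"`).
#' @param aggregation texture aggregation, see [texture_features()].
#' @return named numeric vector of 376 features.
#' @export
wavelet_feature_block <- function(volume, mask, filters = wavelet_filters(),
                                  bin_policy = c("match_level_count", "fixed_width"),
                                  bin_width = 25, boundary = "symmetric",
                                  aggregation = "mean_per_direction") {
  bin_policy <- match.arg(bin_policy)
  check_aligned(volume, mask)
  check_nonempty(mask)
  g_orig <- discretize(volume, mask, bin_width)$n_levels
  bands <- undecimated_wavelet_3d(volume, filters, boundary)
  out <- numeric(0)
  for (b in WAVELET_BANDS) {
    sub <- bands[[b]]
    vals <- sub$data[mask$data]
    rng <- max(vals) - min(vals)
    bw <- if (bin_policy == "fixed_width") bin_width
      else if (rng > 0) rng / g_orig else 1
    fo <- first_order_features(vals, bw)
    roi <- discretize(sub, mask, bw)
    tx <- texture_features(roi, aggregation = aggregation)
    blk <- c(fo, tx)
    names(blk) <- paste0(b, "_", names(blk))
    out <- c(out, blk)
  }
  out
}
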