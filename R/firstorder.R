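# First-order (histogram) statistics of the masked intensity distribution.
# Moments are population moments (1/N); kurtosis is the non-excess Pearson
# form, so a large normal sample scores about 3. Entropy and uniformity are
# computed on the fixed-bin-width histogram used for texture discretization,
# with base-2 logarithms.

FIRST_ORDER_NAMES <- c(
  "Energy", "Entropy", "Kurtosis", "Maximum", "Mean",
  "Mean Absolute Deviation", "Median", "Minimum", "Range", "RMS Value",
  "Skewness", "Standard Deviation", "Uniformity", "Variance")

#' First-order statistical features
#'
#' Computes the 14 first-order features of an intensity sample: Energy,
#' Entropy, Kurtosis, Maximum, Mean, Mean Absolute Deviation, Median,
#' Minimum, Range, RMS Value, Skewness, Standard Deviation, Uniformity and
#' Variance. Entropy (bits) and Uniformity are computed on the histogram
#' with bins of `bin_width`, anchored at the sample minimum; all moments
#' are population (1/N) moments. Skewness and kurtosis of a constant sample
#' are defined as 0 so feature vectors stay finite.
#'
#' @param intensities numeric vector of masked voxel intensities (length
#'   >= 1), e.g. from [extract_masked_intensities()].
#' @param bin_width histogram bin width for Entropy/Uniformity (default 25).
#' @return named numeric vector of the 14 features, in fixed order.
#' @export
first_order_features <- function(intensities, bin_width = 25) {
  x <- as.numeric(intensities)
  if (length(x) == 0L) empty_roi_error("no intensities supplied")
  if (any(!is.finite(x))) extraction_error("non-finite intensity encountered")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- bin_probabilities(x, bin_width)
  out <- c(
    "Energy" = sum(x^2),
    "Entropy" = -sum(p * log2(p)),
    "Kurtosis" = if (m2 > 0) m4 / m2^2 else 0,
    "Maximum" = max(x),
    "Mean" = mu,
    "Mean Absolute Deviation" = mean(abs(x - mu)),
    "Median" = stats::median(x),
    "Minimum" = min(x),
    "Range" = max(x) - min(x),
    "RMS Value" = sqrt(mean(x^2)),
    "Skewness" = if (m2 > 0) m3 / m2^1.5 else 0,
    "Standard Deviation" = sqrt(m2),
    "Uniformity" = sum(p^2),
    "Variance" = m2)
  out[FIRST_ORDER_NAMES]
}
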