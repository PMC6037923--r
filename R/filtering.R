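# Separable 1-D correlation along one axis of a 3-D array, used by both the
# undecimated wavelet decomposition and the smoothed-gradient surface-area
# estimator. The kernel is applied by correlation (no flip):
#   out(i) = sum_p k[p] * x(i + p - 1 - c),  c = floor((len(k) - 1) / 2),
# so odd kernels are centred and even kernels lean one sample left.

pad_indices <- function(n, left, right, boundary) {
  core <- seq_len(n)
  if (left == 0L && right == 0L) return(core)
  if (left > n || right > n)
    parameter_error("filter is too long for this volume dimension")
  switch(boundary,
    symmetric = c(rev(seq_len(left)), core, n + 1L - rev(seq_len(right))),
    periodic = c(n - rev(seq_len(left)) + 1L, core, seq_len(right)),
    zero = c(rep(NA_integer_, left), core, rep(NA_integer_, right)),
    parameter_error(sprintf("unknown boundary mode '%s'", boundary)))
}

correlate_axis <- function(arr, kernel, axis, boundary = "symmetric") {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  nk <- length(kernel)
  c0 <- (nk - 1L) %/% 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  n <- dp[1]
  m <- matrix(a, nrow = n)
  idx <- pad_indices(n, c0, nk - 1L - c0, boundary)
  padded <- m[idx, , drop = FALSE]
  padded[is.na(padded)] <- 0  # zero boundary
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (p in seq_len(nk)) {
    if (kernel[p] != 0)
      out <- out + kernel[p] * padded[(p - 1L) + seq_len(n), , drop = FALSE]
  }
  inv <- order(perm)
  aperm(array(out, dim = dp), inv)
}

gaussian_kernel <- function(sigma, max_radius = Inf) {
  # truncated at 3 sigma, renormalized to sum 1
  r <- min(max(1L, ceiling(3 * sigma)), max_radius)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}
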