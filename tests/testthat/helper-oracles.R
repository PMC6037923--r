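# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops, not the package's vectorized paths.

# co-occurrence: explicit double loop over every voxel pair
oracle_glcm <- function(grid, d, G, symmetric = TRUE) {
  dims <- dim(grid)
  counts <- matrix(0, G, G)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    a <- grid[i, j, k]
    if (a == 0) next
    i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
    if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2] || k2 < 1 || k2 > dims[3]) next
    b <- grid[i2, j2, k2]
    if (b == 0) next
    counts[a, b] <- counts[a, b] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0) return(counts)
  counts / sum(counts)
}

# run lengths: walk every line in the direction from its entry voxel
oracle_glrlm <- function(grid, d, G) {
  dims <- dim(grid)
  inside <- function(v) all(v >= 1) && all(v <= dims)
  runs_lev <- integer(0); runs_len <- integer(0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    v <- c(i, j, k)
    if (inside(v - d)) next  # not a line start
    cur_lev <- 0L; cur_len <- 0L
    while (inside(v)) {
      lev <- grid[v[1], v[2], v[3]]
      if (lev == cur_lev && lev > 0L) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_lev > 0L) { runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len) }
        cur_lev <- lev; cur_len <- if (lev > 0L) 1L else 0L
      }
      v <- v + d
    }
    if (cur_lev > 0L) { runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len) }
  }
  lmax <- max(runs_len, 1L)
  counts <- matrix(0, G, lmax)
  for (r in seq_along(runs_lev))
    counts[runs_lev[r], runs_len[r]] <- counts[runs_lev[r], runs_len[r]] + 1
  structure(list(counts = counts, n_runs = length(runs_lev),
                 n_voxels = sum(grid > 0)),
            class = "glrlm_matrix")
}

# first-order statistics written out longhand
oracle_first_order <- function(x, bw) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lev <- floor((x - min(x)) / bw)
  p <- as.numeric(base::table(lev)) / n
  c("Energy" = sum(x * x),
    "Entropy" = -sum(p * log(p, base = 2)),
    "Kurtosis" = if (m2 > 0) m4 / (m2 * m2) else 0,
    "Maximum" = max(x),
    "Mean" = mu,
    "Mean Absolute Deviation" = sum(abs(x - mu)) / n,
    "Median" = stats::median(x),
    "Minimum" = min(x),
    "Range" = diff(range(x)),
    "RMS Value" = sqrt(sum(x * x) / n),
    "Skewness" = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    "Standard Deviation" = sqrt(m2),
    "Uniformity" = sum(p * p),
    "Variance" = m2)
}

# barycentric-sign point-in-triangle test (independent of the parity code)
oracle_in_triangle <- function(px, py, tri) {
  sign_area <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- sign_area(px, py, tri[1, 1], tri[1, 2], tri[2, 1], tri[2, 2])
  d2 <- sign_area(px, py, tri[2, 1], tri[2, 2], tri[3, 1], tri[3, 2])
  d3 <- sign_area(px, py, tri[3, 1], tri[3, 2], tri[1, 1], tri[1, 2])
  !((d1 < 0 || d2 < 0 || d3 < 0) && (d1 > 0 || d2 > 0 || d3 > 0))
}

# small random discretized ROI for texture oracle checks
random_roi <- function(dims = c(5, 5, 5), G = 4, mask_frac = 0.8, seed = 1) {
  set.seed(seed)
  vol <- voxel_volume(array(runif(prod(dims)) * G * 25, dim = dims))
  m <- array(runif(prod(dims)) < mask_frac, dim = dims)
  if (!any(m)) m[1] <- TRUE
  mask <- segmentation_mask(m)
  discretize(vol, mask, 25)
}
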