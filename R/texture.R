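# Gray-level co-occurrence (GLCM) and run-length (GLRLM) texture analysis
# in 3-D. Displacements cover the 26-neighborhood: 13 direction vectors,
# one from each antipodal pair, at a distance of one voxel in index space
# (offsets are lattice steps; grid anisotropy does not enter the offsets).
# Features are computed per direction and averaged with equal weight, or
# optionally on matrices merged across directions.

#' The 13 unique 3-D displacement directions
#'
#' One representative from each antipodal pair of the 26-neighborhood; the
#' set together with its negatives covers all 26 neighbors. Components are
#' in {-1, 0, 1} and the first nonzero component of each vector is +1.
#'
#' @return a 13 x 3 integer matrix, one direction per row.
#' @export
direction_set <- function() {
  dirs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0L)) next
    if (d[d != 0][1] > 0) dirs[[length(dirs) + 1L]] <- d
  }
  m <- do.call(rbind, dirs)
  storage.mode(m) <- "integer"
  m
}

GLCM_FEATURE_NAMES <- c(
  "Autocorrelation", "Cluster Prominence", "Cluster Shade",
  "Cluster Tendency", "Contrast", "Correlation", "Difference Entropy",
  "Dissimilarity", "GLCM Energy", "GLCM Entropy", "Homogeneity 1",
  "Homogeneity 2", "Informational Measure of Correlation 1",
  "Informational Measure of Correlation 2",
  "Inverse Difference Moment Normalized", "Inverse Difference Normalized",
  "Inverse Variance", "Maximum Probability", "Sum Average", "Sum Entropy",
  "Sum Variance")

GLRLM_FEATURE_NAMES <- c(
  "Short Run Emphasis", "Long Run Emphasis", "Gray Level Nonuniformity",
  "Run Length Nonuniformity", "Run Percentage",
  "Low Gray Level Run Emphasis", "High Gray Level Run Emphasis",
  "Short Run Low Gray Level Emphasis", "Short Run High Gray Level Emphasis",
  "Long Run Low Gray Level Emphasis", "Long Run High Gray Level Emphasis")

TEXTURE_FEATURE_NAMES <- c(GLCM_FEATURE_NAMES, "GLCM Variance",
                           GLRLM_FEATURE_NAMES)

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts pairs of gray levels at displacement `direction * distance`;
#' both voxels of a pair must lie inside the mask. With `symmetric = TRUE`
#' (default) each pair is counted in both orders, making the matrix
#' symmetric. Counts are normalized to probabilities. If no valid pair
#' exists in the direction, an all-zero matrix is returned (flagged by a
#' zero `n_pairs` attribute) and is excluded from feature aggregation.
#'
#' @param roi a `discretized_roi` from [discretize()].
#' @param direction integer length-3 displacement with components in
#'   {-1, 0, 1}, typically a row of [direction_set()].
#' @param distance displacement length in voxels (default 1).
#' @param symmetric count each pair in both orders (default TRUE).
#' @return a G x G probability matrix with attribute `n_pairs`.
#' @export
glcm <- function(roi, direction, distance = 1L, symmetric = TRUE) {
  g <- roi$n_levels
  d <- as.integer(direction) * as.integer(distance)
  dims <- dim(roi$grid)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - d[a]); hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) integer(0) else lo:hi
  })
  zero <- matrix(0, g, g)
  if (any(lengths(rng) == 0L))
    return(structure(zero, n_pairs = 0L, class = c("glcm_matrix", "matrix")))
  a <- roi$grid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- roi$grid[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
  w <- a > 0L & b > 0L
  if (!any(w))
    return(structure(zero, n_pairs = 0L, class = c("glcm_matrix", "matrix")))
  counts <- tabulate((a[w] - 1L) * g + b[w], nbins = g * g)
  m <- matrix(counts, g, g, byrow = TRUE)  # row = level of first voxel
  if (symmetric) m <- m + t(m)
  structure(m / sum(m), n_pairs = sum(w) * (1L + symmetric),
            class = c("glcm_matrix", "matrix"))
}

# the 21 Haralick-style features plus GLCM Variance on one probability matrix
glcm_features_single <- function(p) {
  g <- nrow(p)
  i <- seq_len(g)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sig_x <- sqrt(sum((i - mu_x)^2 * px)); sig_y <- sqrt(sum((i - mu_y)^2 * py))
  ii <- matrix(i, g, g); jj <- t(ii)
  diffm <- ii - jj
  summ <- ii + jj
  auto <- sum(ii * jj * p)
  # diagonal and cross-diagonal marginals
  k_sum <- 2:(2 * g)
  p_sum <- vapply(k_sum, function(k) sum(p[summ == k]), numeric(1))
  k_diff <- 0:(g - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(diffm) == k]), numeric(1))
  plog <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- plog(p)
  pxy_prod <- outer(px, py)
  pos <- p > 0 & pxy_prod > 0
  hxy1 <- -sum(p[pos] * log2(pxy_prod[pos]))
  hxy2 <- plog(pxy_prod)
  hx <- plog(px); hy <- plog(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  sum_avg <- sum(k_sum * p_sum)
  corr <- if (sig_x > 0 && sig_y > 0) (auto - mu_x * mu_y) / (sig_x * sig_y) else 0
  offdiag <- diffm != 0
  c(
    "Autocorrelation" = auto,
    "Cluster Prominence" = sum((summ - mu_x - mu_y)^4 * p),
    "Cluster Shade" = sum((summ - mu_x - mu_y)^3 * p),
    "Cluster Tendency" = sum((summ - mu_x - mu_y)^2 * p),
    "Contrast" = sum(diffm^2 * p),
    "Correlation" = corr,
    "Difference Entropy" = plog(p_diff),
    "Dissimilarity" = sum(abs(diffm) * p),
    "GLCM Energy" = sum(p^2),
    "GLCM Entropy" = hxy,
    "Homogeneity 1" = sum(p / (1 + abs(diffm))),
    "Homogeneity 2" = sum(p / (1 + diffm^2)),
    "Informational Measure of Correlation 1" = imc1,
    "Informational Measure of Correlation 2" = imc2,
    "Inverse Difference Moment Normalized" = sum(p / (1 + diffm^2 / g^2)),
    "Inverse Difference Normalized" = sum(p / (1 + abs(diffm) / g)),
    "Inverse Variance" = if (any(offdiag)) sum(p[offdiag] / diffm[offdiag]^2) else 0,
    "Maximum Probability" = max(p),
    "Sum Average" = sum_avg,
    "Sum Entropy" = plog(p_sum),
    "Sum Variance" = sum((k_sum - sum_avg)^2 * p_sum),
    "GLCM Variance" = sum((ii - mu_x)^2 * p))
}

#' Co-occurrence features averaged over directions
#'
#' Computes the 22 co-occurrence features (the 21 Haralick-style features
#' of [glcm()] matrices plus GLCM Variance) on each supplied matrix and
#' averages them with equal weight. Matrices flagged as having no valid
#' pair are excluded from the average. Correlation-type and informational
#' measures on degenerate (zero-variance) matrices are defined as 0.
#'
#' @param matrices a list of matrices from [glcm()] (or a single matrix).
#' @return named numeric vector of 22 features.
#' @export
glcm_features <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  keep <- Filter(function(m) sum(m) > 0, matrices)
  if (length(keep) == 0L)
    empty_roi_error("no co-occurrence matrix has any valid voxel pair")
  vals <- vapply(keep, glcm_features_single,
                 numeric(length(GLCM_FEATURE_NAMES) + 1L))
  out <- rowMeans(vals)
  out[c(GLCM_FEATURE_NAMES, "GLCM Variance")]
}

#' Gray-level run-length matrix for one direction
#'
#' Runs are maximal segments of voxels with equal gray level along the
#' direction; a run terminates when the level changes, the grid ends, or
#' the line leaves the mask (out-of-mask voxels never join a run).
#'
#' @inheritParams glcm
#' @return a list of class `glrlm_matrix`: `counts` (G x Lmax run-count
#'   matrix), `n_runs`, `n_voxels` (masked voxel count).
#' @export
glrlm <- function(roi, direction) {
  check_roi <- sum(roi$mask)
  if (check_roi == 0L) empty_roi_error("empty mask")
  d <- as.integer(direction)
  if (all(d == 0L)) parameter_error("direction must be nonzero")
  dims <- dim(roi$grid)
  n <- prod(dims)
  lin <- seq_len(n) - 1L
  i1 <- lin %% dims[1]
  i2 <- (lin %/% dims[1]) %% dims[2]
  i3 <- lin %/% (dims[1] * dims[2])
  idx <- cbind(i1, i2, i3)  # 0-based
  axis <- which(d != 0L)[1]
  t_along <- idx[, axis] * d[axis]
  base <- idx - tcrossprod(t_along, d)
  m <- max(dims)
  key <- (base[, 1] + m) + (3 * m + 1) * ((base[, 2] + m) +
           (3 * m + 1) * (base[, 3] + m))
  ord <- order(key, t_along)
  lev <- as.vector(roi$grid)[ord]
  ks <- key[ord]
  changed <- c(TRUE, ks[-1] != ks[-n] | lev[-1] != lev[-n])
  grp <- cumsum(changed)
  run_len <- tabulate(grp)
  run_lev <- lev[changed]
  in_mask <- run_lev > 0L
  run_len <- run_len[in_mask]
  run_lev <- run_lev[in_mask]
  g <- roi$n_levels
  lmax <- max(run_len)
  counts <- matrix(tabulate((run_lev - 1L) * lmax + run_len, nbins = g * lmax),
                   g, lmax, byrow = TRUE)
  structure(list(counts = counts, n_runs = length(run_len),
                 n_voxels = check_roi),
            class = "glrlm_matrix")
}

glrlm_features_single <- function(rl) {
  r <- rl$counts
  nr <- rl$n_runs
  np <- rl$n_voxels
  g <- nrow(r); lmax <- ncol(r)
  i2 <- matrix(seq_len(g)^2, g, lmax)
  l2 <- matrix(rep(seq_len(lmax)^2, each = g), g, lmax)
  c(
    "Short Run Emphasis" = sum(r / l2) / nr,
    "Long Run Emphasis" = sum(r * l2) / nr,
    "Gray Level Nonuniformity" = sum(rowSums(r)^2) / nr,
    "Run Length Nonuniformity" = sum(colSums(r)^2) / nr,
    "Run Percentage" = nr / np,
    "Low Gray Level Run Emphasis" = sum(r / i2) / nr,
    "High Gray Level Run Emphasis" = sum(r * i2) / nr,
    "Short Run Low Gray Level Emphasis" = sum(r / (i2 * l2)) / nr,
    "Short Run High Gray Level Emphasis" = sum(r * i2 / l2) / nr,
    "Long Run Low Gray Level Emphasis" = sum(r * l2 / i2) / nr,
    "Long Run High Gray Level Emphasis" = sum(r * i2 * l2) / nr)
}

#' Run-length features averaged over directions
#'
#' Computes the 11 run-length features on each supplied matrix and averages
#' them with equal weight. Normalizations are by the run count, except Run
#' Percentage which divides by the masked voxel count.
#'
#' @param matrices a list of [glrlm()] results (or a single one).
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(matrices) {
  if (inherits(matrices, "glrlm_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) empty_roi_error("no run-length matrices")
  vals <- vapply(matrices, glrlm_features_single,
                 numeric(length(GLRLM_FEATURE_NAMES)))
  rowMeans(vals)[GLRLM_FEATURE_NAMES]
}

# merge a list of GLCMs (probabilities weighted back to counts) / GLRLMs
merge_glcms <- function(matrices) {
  g <- nrow(matrices[[1]])
  total <- matrix(0, g, g)
  for (m in matrices) {
    np <- attr(m, "n_pairs")
    if (np > 0) total <- total + unclass(m) * np
  }
  s <- sum(total)
  if (s == 0) empty_roi_error("no co-occurrence pairs in any direction")
  structure(total / s, n_pairs = s, class = c("glcm_matrix", "matrix"))
}

merge_glrlms <- function(matrices) {
  g <- nrow(matrices[[1]]$counts)
  lmax <- max(vapply(matrices, function(m) ncol(m$counts), integer(1)))
  total <- matrix(0, g, lmax)
  nr <- 0
  for (m in matrices) {
    total[, seq_len(ncol(m$counts))] <- total[, seq_len(ncol(m$counts))] + m$counts
    nr <- nr + m$n_runs
  }
  structure(list(counts = total, n_runs = nr,
                 n_voxels = matrices[[1]]$n_voxels),
            class = "glrlm_matrix")
}

#' All 33 texture features of a discretized region
#'
#' Builds co-occurrence and run-length matrices for the 13 directions of
#' [direction_set()] and returns the 22 co-occurrence plus 11 run-length
#' features.
#'
#' @param roi a `discretized_roi` from [discretize()].
#' @param aggregation `"mean_per_direction"` (default): features computed
#'   per direction and averaged; `"merged"`: matrices pooled across
#'   directions before a single feature computation.
#' @param distance co-occurrence displacement in voxels (default 1).
#' @return named numeric vector of 33 features.
#' @export
texture_features <- function(roi,
                             aggregation = c("mean_per_direction", "merged"),
                             distance = 1L) {
  aggregation <- match.arg(aggregation)
  dirs <- direction_set()
  glcms <- lapply(seq_len(nrow(dirs)), function(r) glcm(roi, dirs[r, ], distance))
  glrlms <- lapply(seq_len(nrow(dirs)), function(r) glrlm(roi, dirs[r, ]))
  if (aggregation == "merged") {
    glcms <- list(merge_glcms(glcms))
    glrlms <- list(merge_glrlms(glrlms))
  }
  cooc <- glcm_features(glcms)
  runs <- glrlm_features(glrlms)
  c(cooc, runs)[TEXTURE_FEATURE_NAMES]
}
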