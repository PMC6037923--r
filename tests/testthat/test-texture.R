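line_roi <- function(levels_vec) {
  # 1 x 1 x n ROI with prescribed gray levels (via bin width 1 on integers)
  n <- length(levels_vec)
  vol <- voxel_volume(array(as.double(levels_vec), dim = c(1, 1, n)))
  mask <- segmentation_mask(array(TRUE, dim = c(1, 1, n)))
  discretize(vol, mask, bin_width = 1)
}

test_that("the direction set covers the 26-neighborhood without antipodal pairs", {
  d <- direction_set()
  expect_equal(nrow(d), 13L)
  expect_true(all(d %in% -1:1))
  expect_false(any(rowSums(abs(d)) == 0))
  keys <- apply(d, 1, paste, collapse = ",")
  anti <- apply(-d, 1, paste, collapse = ",")
  expect_length(intersect(keys, anti), 0)
  expect_length(unique(c(keys, anti)), 26L)
})

test_that("the alternating two-level line yields the textbook co-occurrence matrix", {
  roi <- line_roi(c(1, 2, 1, 2))
  m <- glcm(roi, c(0, 0, 1))
  expect_equal(unclass(m)[1, 2], 0.5)
  expect_equal(unclass(m)[2, 1], 0.5)
  expect_equal(unclass(m)[1, 1], 0)
  expect_equal(unclass(m)[2, 2], 0)
  f <- glcm_features(m)
  expect_equal(unname(f["Contrast"]), 1.0)
  expect_equal(unname(f["GLCM Energy"]), 0.5)
  expect_equal(unname(f["Maximum Probability"]), 0.5)
  expect_equal(unname(f["GLCM Entropy"]), 1.0)
  expect_equal(unname(f["Autocorrelation"]), 2.0)
})

test_that("a constant region has degenerate texture", {
  roi <- line_roi(rep(4, 5))
  m <- glcm(roi, c(0, 0, 1))
  expect_equal(unclass(m)[1, 1], 1)
  f <- glcm_features(m)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["GLCM Energy"]), 1)
  expect_equal(unname(f["Maximum Probability"]), 1)
  expect_equal(unname(f["Correlation"]), 0)  # zero-variance guard
})

test_that("no-pair directions are flagged and excluded from aggregation", {
  roi <- line_roi(c(1, 2))
  m <- glcm(roi, c(1, 0, 0))  # 1-voxel-wide axis: no pair exists
  expect_equal(attr(m, "n_pairs"), 0L)
  expect_true(all(unclass(m) == 0))
  expect_error(glcm_features(list(m)), class = "ctr_empty_roi_error")
})

test_that("co-occurrence matrices match the brute-force oracle on random regions", {
  dirs <- direction_set()
  for (s in 1:20) {
    roi <- random_roi(seed = s)
    for (r in seq_len(nrow(dirs))) {
      got <- glcm(roi, dirs[r, ])
      want <- oracle_glcm(roi$grid, dirs[r, ], roi$n_levels)
      expect_lt(max(abs(unclass(got) - want)), 1e-9)
    }
  }
})

test_that("run-length matrices reproduce hand-segmented runs", {
  roi <- line_roi(c(1, 1, 2, 2, 2))
  rl <- glrlm(roi, c(0, 0, 1))
  expect_equal(rl$n_runs, 2L)
  expect_equal(rl$counts[1, 2], 1)
  expect_equal(rl$counts[2, 3], 1)
  expect_equal(sum(rl$counts), 2)
  f <- glrlm_features(rl)
  expect_equal(unname(f["Short Run Emphasis"]), (1 / 4 + 1 / 9) / 2,
               tolerance = 1e-9)
  expect_equal(unname(f["Long Run Emphasis"]), 6.5)
  expect_equal(unname(f["Run Percentage"]), 0.4)
  expect_equal(unname(f["Gray Level Nonuniformity"]), 1.0)
  expect_equal(unname(f["Run Length Nonuniformity"]), 1.0)

  roi5 <- line_roi(rep(2, 5))
  f5 <- glrlm_features(glrlm(roi5, c(0, 0, 1)))
  expect_equal(unname(f5["Run Percentage"]), 0.2)
  expect_equal(unname(f5["Long Run Emphasis"]), 25)
})

test_that("runs break at mask boundaries", {
  vol <- voxel_volume(array(7, dim = c(1, 1, 5)))
  m <- array(TRUE, dim = c(1, 1, 5)); m[1, 1, 3] <- FALSE
  roi <- discretize(vol, segmentation_mask(m), 1)
  rl <- glrlm(roi, c(0, 0, 1))
  expect_equal(rl$n_runs, 2L)           # two runs of length 2
  expect_equal(rl$counts[1, 2], 2)
})

test_that("run-length matrices match the line-scan oracle on random regions", {
  dirs <- direction_set()
  for (s in 1:20) {
    roi <- random_roi(dims = c(4, 4, 4), seed = 100 + s)
    for (r in seq_len(nrow(dirs))) {
      got <- glrlm(roi, dirs[r, ])
      want <- oracle_glrlm(roi$grid, dirs[r, ], roi$n_levels)
      expect_equal(got$n_runs, want$n_runs)
      expect_equal(got$n_voxels, want$n_voxels)
      expect_lt(max(abs(got$counts - want$counts)), 1e-9)
      expect_lt(max(abs(unlist(glrlm_features(got)) -
                          unlist(glrlm_features(want)))), 1e-9)
    }
  }
})

test_that("all 33 texture features are finite on assorted regions", {
  cases <- list(line_roi(rep(1, 4)), line_roi(c(1, 2, 1, 2)),
                random_roi(seed = 2), random_roi(G = 12, seed = 3))
  for (roi in cases) {
    f <- texture_features(roi)
    expect_length(f, 33L)
    expect_true(all(is.finite(unlist(f))))
  }
})

test_that("entropy-type features are invariant to relabeling gray levels", {
  roi <- random_roi(G = 4, seed = 44)
  f1 <- texture_features(roi)
  # reverse the level labels consistently
  roi2 <- roi
  roi2$grid[roi$grid > 0] <- roi$n_levels + 1L - roi$grid[roi$grid > 0]
  f2 <- texture_features(roi2)
  ent <- c("GLCM Entropy", "Sum Entropy", "Difference Entropy",
           "GLCM Energy", "Maximum Probability", "Contrast")
  expect_equal(f1[ent], f2[ent], tolerance = 1e-9)
})

test_that("merged-matrix aggregation stays finite and close in kind", {
  roi <- random_roi(seed = 77)
  f <- texture_features(roi, aggregation = "merged")
  expect_length(f, 33L)
  expect_true(all(is.finite(unlist(f))))
})
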