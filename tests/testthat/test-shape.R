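single_voxel_mask <- function(spacing = c(1, 1, 1)) {
  m <- array(FALSE, dim = c(3, 3, 3)); m[2, 2, 2] <- TRUE
  segmentation_mask(m, spacing = spacing)
}

cube_mask <- function(n = 10, pad = 3, spacing = c(1, 1, 1)) {
  d <- n + 2 * pad
  m <- array(FALSE, dim = rep(d, 3))
  m[pad + seq_len(n), pad + seq_len(n), pad + seq_len(n)] <- TRUE
  segmentation_mask(m, spacing = spacing)
}

test_that("a single voxel reproduces its closed-form shape summary", {
  f <- shape_features(single_voxel_mask())
  expect_equal(unname(f["Volume"]), 1)
  expect_equal(unname(f["Surface Area"]), 6)
  expect_equal(unname(f["Maximum 3D diameter"]), 0)
  expect_equal(unname(f["Surface-to-Volume Ratio"]), 6)
})

test_that("the 10-voxel cube matches closed-form values", {
  f <- shape_features(cube_mask(10))
  expect_named(f, c("Compactness1", "Compactness2", "Maximum 3D diameter",
                    "Spherical Disproportion", "Sphericity", "Surface Area",
                    "Surface-to-Volume Ratio", "Volume"))
  expect_equal(unname(f["Volume"]), 1000)
  expect_equal(unname(f["Surface Area"]), 600)
  expect_equal(unname(f["Sphericity"]), pi^(1 / 3) * 6000^(2 / 3) / 600,
               tolerance = 1e-6)
  expect_equal(unname(f["Sphericity"]), 0.80600, tolerance = 1e-4)
  expect_equal(unname(f["Compactness2"]), pi / 6, tolerance = 1e-6)
  expect_equal(unname(f["Compactness2"]), 0.52360, tolerance = 1e-4)
  expect_equal(unname(f["Spherical Disproportion"]), 1.24070, tolerance = 1e-4)
  expect_equal(unname(f["Maximum 3D diameter"]), 9 * sqrt(3), tolerance = 1e-9)
})

test_that("sphericity identities hold on arbitrary masks", {
  set.seed(5)
  for (rep in 1:10) {
    m <- array(runif(4 * 5 * 6) < 0.4, dim = c(4, 5, 6))
    if (!any(m)) m[1] <- TRUE
    mask <- segmentation_mask(m, spacing = runif(3, 0.5, 3))
    for (method in c("face_count", "gradient")) {
      f <- shape_features(mask, method)
      expect_equal(unname(f["Compactness2"]), unname(f["Sphericity"])^3,
                   tolerance = 1e-9)
      expect_equal(unname(f["Spherical Disproportion"] * f["Sphericity"]), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("shape features scale correctly with voxel spacing", {
  a <- shape_features(cube_mask(6, spacing = c(1, 1, 1)))
  b <- shape_features(cube_mask(6, spacing = c(2, 2, 2)))
  expect_equal(unname(b["Volume"] / a["Volume"]), 8)
  expect_equal(unname(b["Surface Area"] / a["Surface Area"]), 4)
  expect_equal(unname(b["Maximum 3D diameter"] / a["Maximum 3D diameter"]), 2)
  dimless <- c("Compactness2", "Sphericity", "Spherical Disproportion")
  expect_equal(a[dimless], b[dimless], tolerance = 1e-9)
})

test_that("digitized balls approach unit sphericity under the gradient estimator", {
  sph <- vapply(c(3, 12, 20), function(r) {
    ph <- make_phantom(phantom_spec(shape = rep(2L * r + 9L, 3),
                                    mask_shape = "sphere", mask_size = r,
                                    texture = "constant", seed = 1))
    unname(shape_features(ph$mask, "gradient")["Sphericity"])
  }, numeric(1))
  expect_gte(sph[2], 0.9); expect_lte(sph[2], 1.0)
  expect_gte(sph[3], 0.9); expect_lte(sph[3], 1.0)
  # finer digitization comes closer to the analytic limit than coarse
  expect_lt(abs(1 - sph[3]), abs(1 - sph[1]))
  expect_lt(abs(1 - sph[3]), 0.02)
})

test_that("face counting is exact for a cube but overestimates curved surfaces", {
  ph <- make_phantom(phantom_spec(shape = c(49L, 49L, 49L), mask_shape = "sphere",
                                  mask_size = 20, texture = "constant", seed = 1))
  a_face <- unname(shape_features(ph$mask, "face_count")["Surface Area"])
  a_grad <- unname(shape_features(ph$mask, "gradient")["Surface Area"])
  ideal <- 4 * pi * 20^2
  expect_gt(a_face / ideal, 1.4)          # staircase limit 3/2
  expect_lt(abs(a_grad - ideal) / ideal, 0.03)
})
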