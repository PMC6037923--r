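test_that("digitized sphere and ellipsoid volumes match the continuum formula", {
  ph <- make_phantom(phantom_spec(shape = c(33L, 33L, 33L), mask_shape = "sphere",
                                  mask_size = 12, texture = "constant", seed = 1))
  expect_lt(abs(sum(ph$mask$data) - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3),
            0.05)

  pe <- make_phantom(phantom_spec(shape = c(40L, 36L, 30L),
                                  mask_shape = "ellipsoid",
                                  mask_size = c(15, 12, 10),
                                  texture = "constant", seed = 1))
  expect_lt(abs(sum(pe$mask$data) - 4 / 3 * pi * 15 * 12 * 10) /
              (4 / 3 * pi * 15 * 12 * 10), 0.05)
})

test_that("phantoms are exactly reproducible under a seed and differ across seeds", {
  s <- phantom_spec(seed = 99)
  a <- make_phantom(s); b <- make_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c2 <- make_phantom(phantom_spec(seed = 100))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("a constant-texture phantom has degenerate first-order statistics", {
  ph <- make_phantom(phantom_spec(shape = c(16L, 16L, 16L), mask_size = c(5, 4, 3),
                                  texture = "constant",
                                  texture_params = list(value = 40), seed = 2))
  fv <- extract_all(ph$volume, ph$mask)
  expect_equal(unname(fv$values["Entropy"]), 0)
  expect_equal(unname(fv$values["Variance"]), 0)
  expect_equal(unname(fv$values["Mean"]), 40)
})

test_that("a mask larger than the grid is rejected", {
  expect_error(phantom_spec(shape = c(16L, 16L, 16L), mask_shape = "sphere",
                            mask_size = 10),
               class = "ctr_parameter_error")
})

test_that("the default cohort mirrors the skewed four-class sizes", {
  tab <- make_cohort(cohort_spec(seed = 1))
  expect_equal(as.integer(base::table(tab$label)[c("adenocarcinoma",
                                                   "large cell",
                                                   "squamous cell", "NOS")]),
               c(40L, 108L, 110L, 59L))
  expect_length(feature_names(tab), 431L)
  tab2 <- make_cohort(cohort_spec(seed = 1))
  expect_identical(feature_matrix(tab), feature_matrix(tab2))
})

test_that("a zero-effect cohort classifies at chance", {
  tab <- make_cohort(cohort_spec(class_sizes = c(A = 50, B = 50, C = 50, D = 50),
                                 effect_size = 0, seed = 21))
  cv <- cross_validate(tab, svm_params(gamma = NULL), folds = 5, seed = 2)
  se3 <- 3 * sqrt(0.25 * 0.75 / nrow(tab))
  expect_lt(abs(cv$metrics$accuracy - 0.25), se3)
})

test_that("checkerboard and correlated-noise textures separate in GLCM contrast", {
  contrast_of <- function(spec) {
    ph <- make_phantom(spec)
    roi <- discretize(ph$volume, ph$mask, 25)
    unname(texture_features(roi)["Contrast"])
  }
  chk <- vapply(1:6, function(s) contrast_of(
    phantom_spec(shape = c(20L, 20L, 20L), mask_size = c(6, 5, 4),
                 texture = "checkerboard", seed = s)), numeric(1))
  gau <- vapply(1:6, function(s) contrast_of(
    phantom_spec(shape = c(20L, 20L, 20L), mask_size = c(6, 5, 4),
                 texture = "gaussian_field", seed = s)), numeric(1))
  pooled_sd <- sqrt((stats::var(chk) + stats::var(gau)) / 2)
  expect_gt(abs(mean(chk) - mean(gau)), max(pooled_sd, 1e-9))
})

test_that("image-mode cohorts run the extractor end to end", {
  tab <- make_cohort(cohort_spec(class_sizes = c(adenocarcinoma = 2,
                                                 `large cell` = 2,
                                                 `squamous cell` = 2, NOS = 2),
                                 mode = "images", seed = 3))
  expect_equal(nrow(tab), 8L)
  expect_length(feature_names(tab), 431L)
  expect_true(all(is.finite(feature_matrix(tab))))
})
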