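small_phantom_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(phantom_spec(shape = c(20L, 20L, 20L),
                                      mask_size = c(6, 5, 4), seed = 5))
      cache <<- list(ph = ph, fv = extract_all(ph$volume, ph$mask,
                                               subject_id = "P1"))
    }
    cache
  }
})

test_that("the full extractor emits 431 uniquely named finite features in blocks 14/8/33/376", {
  fv <- small_phantom_features()$fv
  expect_s3_class(fv, "feature_vector")
  expect_length(fv$values, 431L)
  expect_false(anyDuplicated(names(fv$values)) > 0)
  expect_true(all(is.finite(fv$values)))
  expect_equal(as.integer(base::table(fv$blocks)[c("firstorder", "shape",
                                                   "texture", "wavelet")]),
               c(14L, 8L, 33L, 376L))
  expect_identical(names(fv$values), radiomic_feature_names())
})

test_that("extraction is deterministic", {
  env <- small_phantom_features()
  again <- extract_all(env$ph$volume, env$ph$mask, subject_id = "P1")
  expect_identical(env$fv$values, again$values)
})

test_that("the conventional subset keeps exactly the 21 printed names", {
  fv <- small_phantom_features()$fv
  tab <- feature_table(list(fv, fv), labels = c("adenocarcinoma", "NOS"))
  sub <- select_normal_subset(tab)
  expect_equal(ncol(sub), 23L)  # id + 21 + label
  expect_setequal(feature_names(sub),
                  c("Energy", "Entropy", "Kurtosis", "Maximum", "Mean",
                    "Mean Absolute Deviation", "Median", "Minimum", "Range",
                    "RMS Value", "Skewness", "Standard Deviation",
                    "Uniformity", "Variance", "Compactness",
                    "Maximum 3D diameter", "Spherical Disproportion",
                    "Sphericity", "Surface Area", "Surface-to-Volume Ratio",
                    "Volume"))
  expect_equal(sub$Compactness, rep(unname(fv$values["Compactness1"]), 2))
  expect_identical(select_normal_subset(sub)[, -1], sub[, -1])

  broken <- tab[, setdiff(colnames(tab), "Sphericity")]
  class(broken) <- c("feature_table", "data.frame")
  expect_error(select_normal_subset(broken), class = "ctr_schema_error")
})

test_that("CSV round-trip preserves names, order, values and labels", {
  set.seed(31)
  x <- matrix(rnorm(3 * 431), 3, 431,
              dimnames = list(NULL, radiomic_feature_names()))
  tab <- feature_table(x, labels = c("adenocarcinoma", "large cell", "NOS"),
                       subject_id = c("a", "b", "c"))
  f <- tempfile(fileext = ".csv")
  write_table(tab, f)
  hdr <- readLines(f, n = 1)
  expect_false(grepl(" ", hdr))   # machine-safe aliases on disk
  back <- read_table(f)
  expect_identical(feature_names(back), feature_names(tab))
  expect_identical(back$subject_id, tab$subject_id)
  expect_identical(as.character(back$label), as.character(tab$label))
  expect_lt(max(abs(feature_matrix(back) - feature_matrix(tab))), 1e-12)
  unlink(f)
})

test_that("malformed CSV inputs raise format/schema errors", {
  f <- tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_table(f), class = "ctr_format_error")
  writeLines(c("subject_id,Mean,Mean,label", "a,1,2,adenocarcinoma"), f)
  expect_error(read_table(f), class = "ctr_schema_error")
  unlink(f)
  expect_error(read_table(tempfile()), class = "ctr_format_error")
})

test_that("feature aliases are reversible for every canonical name", {
  nm <- radiomic_feature_names()
  al <- feature_alias(nm)
  expect_false(any(grepl("[^A-Za-z0-9_]", al)))
  expect_false(anyDuplicated(al) > 0)
  expect_identical(display_name(al), nm)
})
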