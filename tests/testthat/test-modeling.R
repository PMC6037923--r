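separable_cohort <- function(seed = 11) {
  make_cohort(cohort_spec(class_sizes = c(A = 50, B = 50, C = 50, D = 50),
                          n_features = 10, effect_size = 6,
                          signal_features = paste0("F", 1:10), seed = seed))
}

test_that("a perfect confusion matrix yields unit metrics", {
  cm <- diag(25, 4)
  dimnames(cm) <- list(truth = letters[1:4], predicted = letters[1:4])
  m <- ctradiomics:::confusion_metrics(as.table(cm))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_sensitivity, 1)
  expect_equal(m$macro_specificity, 1)
  expect_equal(m$per_class$sensitivity, rep(1, 4))
})

test_that("an always-one-class predictor has macro sensitivity 1/4 on balanced data", {
  cm <- matrix(0, 4, 4, dimnames = list(truth = letters[1:4],
                                        predicted = letters[1:4]))
  cm[, 1] <- 25
  m <- ctradiomics:::confusion_metrics(as.table(cm))
  expect_equal(m$macro_sensitivity, 0.25)
  expect_equal(m$accuracy, 0.25)
})

test_that("cross-validation recovers well-separated classes almost perfectly", {
  cv <- cross_validate(separable_cohort(), svm_params(), folds = 10, seed = 1)
  expect_gte(cv$metrics$accuracy, 0.95)
  expect_equal(sum(cv$confusion), 200)
  expect_equal(as.integer(rowSums(cv$confusion)), rep(50L, 4))
  # metrics come from the pooled confusion matrix: fold order cannot matter
  expect_equal(cv$metrics$accuracy,
               sum(diag(cv$confusion)) / sum(cv$confusion))
})

test_that("permuting labels drops accuracy to chance", {
  tab <- separable_cohort()
  set.seed(2)
  tab$label <- sample(tab$label)
  cv <- cross_validate(tab, svm_params(), folds = 10, seed = 1)
  se3 <- 3 * sqrt(0.25 * 0.75 / nrow(tab))
  expect_lt(abs(cv$metrics$accuracy - 0.25), se3)
})

test_that("a class with fewer rows than folds is rejected", {
  tab <- separable_cohort()
  small <- tab[c(1:5, 51:100, 101:150, 151:200), ]
  class(small) <- c("feature_table", "data.frame")
  expect_error(cross_validate(small, svm_params(), folds = 10, seed = 1),
               class = "ctr_config_error")
})

test_that("one-vs-rest decomposition also separates the classes", {
  cv <- cross_validate(separable_cohort(),
                       svm_params(decomposition = "one_vs_rest"),
                       folds = 5, seed = 1)
  expect_gte(cv$metrics$accuracy, 0.95)
})

test_that("pre-standardized features make standardization a no-op", {
  tab <- separable_cohort()
  x <- scale(feature_matrix(tab))
  tab_z <- feature_table(x, labels = tab$label, subject_id = tab$subject_id)
  a <- cross_validate(tab_z, svm_params(standardize = TRUE), folds = 5, seed = 9)
  b <- cross_validate(tab_z, svm_params(standardize = FALSE), folds = 5, seed = 9)
  expect_gt(sum(diag(b$confusion)) / sum(b$confusion), 0.9)
  expect_equal(a$metrics$accuracy, b$metrics$accuracy, tolerance = 0.05)
})

test_that("a class-indicator feature is ranked first with score 100", {
  set.seed(33)
  n <- 80
  labels <- rep(c("A", "B", "C", "D"), each = n / 4)
  x <- cbind(indicator = as.numeric(labels == "B"),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  rk <- rank_features(feature_table(x, labels = labels))
  expect_equal(rk$feature[1], "indicator")
  expect_equal(rk$importance[1], 100)
  expect_equal(nrow(rk), 6L)
  expect_setequal(rk$rank, 1:6)
  expect_true(all(diff(rk$importance) <= 1e-12))
})

test_that("an informative feature outranks pure noise in almost every replicate", {
  wins <- 0L
  for (s in 1:30) {
    set.seed(400 + s)
    labels <- rep(c("A", "B"), each = 50)
    x <- cbind(informative = rnorm(100) + 2 * (labels == "B"),
               noise = rnorm(100))
    rk <- rank_features(feature_table(x, labels = labels))
    wins <- wins + (rk$feature[1] == "informative")
  }
  expect_gte(wins, 29L)
})

test_that("the rank AUC agrees with an established ROC implementation", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(60)
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    ours <- ctradiomics:::rank_auc(x, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE,
                                          direction = "auto")))
    expect_equal(ours, max(ref, 1 - ref), tolerance = 1e-9)
  }
})

test_that("the continuity-corrected McNemar statistic matches closed form and stats::mcnemar.test", {
  a <- c(rep(TRUE, 10), rep(TRUE, 40), rep(FALSE, 10))
  b <- c(rep(FALSE, 10), rep(TRUE, 40), rep(FALSE, 10))
  mc <- ctradiomics:::mcnemar_paired(a, b)
  expect_equal(mc$b, 10L)
  expect_equal(mc$c, 0L)
  expect_equal(mc$statistic, 8.1)
  ref <- stats::mcnemar.test(base::table(a, b), correct = TRUE)
  expect_equal(mc$statistic, unname(ref$statistic))
  expect_equal(mc$p_value, unname(ref$p.value))

  same <- ctradiomics:::mcnemar_paired(a, a)
  expect_equal(same$p_value, 1)
})

test_that("identical prediction vectors give zero accuracy gap and p = 1", {
  tab <- separable_cohort()
  fold_id <- ctradiomics:::stratified_folds(tab$label, 5, seed = 3)
  r1 <- cross_validate(tab, svm_params(), seed = 3, fold_id = fold_id)
  r2 <- cross_validate(tab, svm_params(), seed = 3, fold_id = fold_id)
  expect_identical(r1$predictions, r2$predictions)
  mc <- ctradiomics:::mcnemar_paired(r1$predictions == r1$truth,
                                     r2$predictions == r2$truth)
  expect_equal(mc$p_value, 1)
})

test_that("radiomic features beat the conventional subset when signal is wavelet-texture only", {
  tab <- make_cohort(cohort_spec(
    class_sizes = c(adenocarcinoma = 50, `large cell` = 50,
                    `squamous cell` = 50, NOS = 50),
    effect_size = 2, seed = 5))
  cmp <- compare_models(tab, svm_params(gamma = NULL), folds = 5, seed = 3)
  expect_gt(cmp$accuracy_difference, 0)
  expect_lt(cmp$mcnemar$p_value, 0.05)
  expect_gt(cmp$radiomic$metrics$accuracy, cmp$normal$metrics$accuracy)
  # identical folds were used for the paired comparison
  expect_identical(cmp$radiomic$fold_id, cmp$normal$fold_id)
})
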