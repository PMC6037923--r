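# Multiclass RBF-SVM classification with stratified k-fold cross
# validation, confusion-matrix metrics, filter-style feature ranking, and
# the radiomic-versus-conventional model comparison. The SVM is fit with
# e1071; features are z-standardized with training-fold statistics so no
# information leaks from held-out folds, and SMOTE (when enabled) is
# likewise applied inside each training fold only.

#' SVM hyperparameters
#'
#' Defaults follow the grid-searched operating point used for the NSCLC
#' histology task: RBF kernel, gamma 1.0, cost 0.1 and optimizer
#' termination tolerance 1e-4.
#'
#' @param gamma RBF kernel width parameter (> 0), or `NULL` to scale it
#'   as 1/p with the feature count p of the model being fit (the common
#'   default for differently sized feature sets).
#' @param cost soft-margin cost C (> 0).
#' @param tolerance optimizer termination tolerance.
#' @param standardize z-standardize features with training-fold statistics.
#' @param decomposition multiclass scheme: `"one_vs_one"` (pairwise voting,
#'   the default of the underlying machine) or `"one_vs_rest"`.
#' @return list of class `svm_params`.
#' @export
svm_params <- function(gamma = 1.0, cost = 0.1, tolerance = 1e-4,
                       standardize = TRUE,
                       decomposition = c("one_vs_one", "one_vs_rest")) {
  if ((!is.null(gamma) && gamma <= 0) || cost <= 0 || tolerance <= 0)
    parameter_error("gamma, cost and tolerance must be positive")
  structure(list(gamma = gamma, cost = cost, tolerance = tolerance,
                 standardize = standardize,
                 decomposition = match.arg(decomposition)),
            class = "svm_params")
}

fit_predict_svm <- function(xtr, ytr, xte, params) {
  gamma <- if (is.null(params$gamma)) 1 / ncol(xtr) else params$gamma
  if (params$decomposition == "one_vs_one") {
    fit <- e1071::svm(xtr, ytr, type = "C-classification", kernel = "radial",
                      gamma = gamma, cost = params$cost,
                      tolerance = params$tolerance, scale = FALSE)
    stats::predict(fit, xte)
  } else {
    lev <- levels(ytr)
    scores <- vapply(lev, function(cl) {
      yb <- factor(ifelse(ytr == cl, "pos", "neg"), levels = c("neg", "pos"))
      fit <- e1071::svm(xtr, yb, type = "C-classification", kernel = "radial",
                        gamma = gamma, cost = params$cost,
                        tolerance = params$tolerance, scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # the decision value is positive for the level named first in the
      # dimname "a/b"; orient so positive means the target class
      if (startsWith(colnames(dv)[1], "pos")) dv[, 1] else -dv[, 1]
    }, numeric(nrow(xte)))
    factor(lev[max.col(scores)], levels = lev)
  }
}

stratified_folds <- function(labels, folds, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold_id
}

confusion_metrics <- function(cm) {
  n <- sum(cm)
  classes <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  list(
    per_class = data.frame(class = classes, sensitivity = sens,
                           specificity = spec, row.names = NULL),
    accuracy = sum(tp) / n,
    macro_sensitivity = mean(sens, na.rm = TRUE),
    macro_specificity = mean(spec, na.rm = TRUE),
    micro_sensitivity = sum(tp) / sum(tp + fn),
    micro_specificity = sum(tn) / sum(tn + fp))
}

#' Stratified k-fold cross-validated SVM classification
#'
#' Splits subjects into stratified folds, and for each fold standardizes
#' features with training statistics, optionally SMOTE-balances the
#' training rows, fits the multiclass RBF-SVM and predicts the held-out
#' rows. Held-out predictions are pooled into one confusion matrix;
#' sensitivity and specificity are one-vs-rest per class and
#' macro-averaged (micro averages are reported alongside).
#'
#' @param table a [feature_table()].
#' @param params an [svm_params()].
#' @param folds number of folds (default 10). Every class needs at least
#'   `folds` rows.
#' @param seed integer seed for the fold assignment (and SMOTE).
#' @param smote apply SMOTE inside each training fold (default FALSE).
#' @param smote_k SMOTE neighbor count.
#' @param fold_id optional externally supplied fold assignment (overrides
#'   `folds`/`seed`), e.g. to compare models on identical splits.
#' @return object of class `cv_report`: pooled `confusion`, `per_fold`
#'   confusions, `metrics`, held-out `predictions` and `truth`, `fold_id`.
#' @export
cross_validate <- function(table, params = svm_params(), folds = 10L,
                           seed = 1L, smote = FALSE, smote_k = 5L,
                           fold_id = NULL) {
  y <- droplevels(table$label)
  if (nlevels(y) < 2L) config_error("need at least two classes")
  if (is.null(fold_id)) {
    if (any(base::table(y) < folds))
      config_error("every class needs at least as many rows as folds")
    fold_id <- stratified_folds(y, folds, seed)
  }
  x <- feature_matrix(table)
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  per_fold <- list()
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    if (smote) {
      tr_tab <- table[!te, , drop = FALSE]
      class(tr_tab) <- c("feature_table", "data.frame")
      tr_tab <- smote(tr_tab, k = smote_k, seed = seed + f)
      xtr <- feature_matrix(tr_tab)
      ytr <- droplevels(tr_tab$label)
    } else {
      xtr <- x[!te, , drop = FALSE]
      ytr <- y[!te]
    }
    xte <- x[te, , drop = FALSE]
    if (params$standardize) {
      mu <- colMeans(xtr)
      sdev <- apply(xtr, 2, stats::sd)
      sdev[sdev == 0 | !is.finite(sdev)] <- 1
      xtr <- sweep(sweep(xtr, 2, mu, "-"), 2, sdev, "/")
      xte <- sweep(sweep(xte, 2, mu, "-"), 2, sdev, "/")
    }
    p <- fit_predict_svm(xtr, factor(ytr, levels = levels(y)), xte, params)
    pred[te] <- p
    per_fold[[as.character(f)]] <- base::table(truth = y[te], predicted = p)
  }
  cm <- base::table(truth = y, predicted = pred)
  structure(list(confusion = cm, per_fold = per_fold,
                 metrics = confusion_metrics(cm),
                 predictions = pred, truth = y, fold_id = fold_id,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat("<cv_report> ", length(x$truth), " subjects, ",
      length(x$per_fold), " folds\n", sep = "")
  cat(sprintf("  accuracy %.3f | macro sensitivity %.3f | macro specificity %.3f\n",
              m$accuracy, m$macro_sensitivity, m$macro_specificity))
  print(x$confusion)
  invisible(x)
}

# orientation-free rank AUC of one feature against a binary split
rank_auc <- function(x, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(x)
  a <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

#' Filter-style feature ranking
#'
#' Scores each feature by the maximum, over classes, of its one-vs-rest
#' ROC area (orientation-free), scaled to 0-100, and ranks features by
#' decreasing score with ties broken by feature name order. A feature that
#' perfectly separates one class from the rest scores 100.
#'
#' @param table a [feature_table()] with >= 2 classes.
#' @param top optionally return only the first `top` rows.
#' @return data frame of class `feature_ranking` with columns `feature`,
#'   `importance`, `rank`.
#' @export
rank_features <- function(table, top = NULL) {
  y <- droplevels(table$label)
  if (nlevels(y) < 2L) config_error("feature ranking needs >= 2 classes")
  x <- feature_matrix(table)
  score <- vapply(seq_len(ncol(x)), function(j) {
    100 * max(vapply(levels(y), function(cl) rank_auc(x[, j], y == cl),
                     numeric(1)))
  }, numeric(1))
  nm <- colnames(x)
  ord <- order(-score, nm)
  out <- data.frame(feature = nm[ord], importance = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), ]
  class(out) <- c("feature_ranking", "data.frame")
  out
}

# continuity-corrected McNemar test on paired correctness indicators
mcnemar_paired <- function(correct_a, correct_b) {
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L)
    return(list(b = b, c = cc, statistic = 0, p_value = 1))
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare the radiomic model with the conventional-feature model
#'
#' Cross-validates the SVM on the full radiomic table and on its
#' 21-feature conventional subset ([select_normal_subset()]) using
#' identical fold assignments, and tests the paired held-out predictions
#' for a difference in accuracy with a continuity-corrected McNemar test.
#'
#' @inheritParams cross_validate
#' @return list of class `model_comparison` with `radiomic` and `normal`
#'   [cross_validate()] reports, `accuracy_difference` (radiomic minus
#'   normal) and `mcnemar` (`b`, `c`, `statistic`, `p_value`).
#' @export
compare_models <- function(table, params = svm_params(), folds = 10L,
                           seed = 1L, smote = FALSE, smote_k = 5L) {
  y <- droplevels(table$label)
  if (any(base::table(y) < folds))
    config_error("every class needs at least as many rows as folds")
  fold_id <- stratified_folds(y, folds, seed)
  full <- cross_validate(table, params, seed = seed, smote = smote,
                         smote_k = smote_k, fold_id = fold_id)
  normal <- cross_validate(select_normal_subset(table), params, seed = seed,
                           smote = smote, smote_k = smote_k,
                           fold_id = fold_id)
  mc <- mcnemar_paired(full$predictions == full$truth,
                       normal$predictions == normal$truth)
  structure(list(radiomic = full, normal = normal,
                 accuracy_difference = full$metrics$accuracy -
                   normal$metrics$accuracy,
                 mcnemar = mc),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  cat(sprintf("  radiomic accuracy %.3f | normal accuracy %.3f | difference %+.3f\n",
              x$radiomic$metrics$accuracy, x$normal$metrics$accuracy,
              x$accuracy_difference))
  cat(sprintf("  McNemar b = %d, c = %d, statistic = %.3f, p = %.4g\n",
              x$mcnemar$b, x$mcnemar$c, x$mcnemar$statistic,
              x$mcnemar$p_value))
  invisible(x)
}
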