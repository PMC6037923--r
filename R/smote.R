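# SMOTE minority oversampling. Synthetic samples interpolate between a
# minority point and one of its k nearest same-class neighbors:
#   s = x + u * (x_nn - x),  u ~ Uniform(0, 1),
# with neighbors found by Euclidean distance on standardized features and
# the interpolation done in the original feature space. Every class is
# grown to the majority class size; original rows pass through unchanged.

#' SMOTE class balancing
#'
#' Oversamples every minority class of a feature table up to the majority
#' class count with the Synthetic Minority Over-sampling Technique.
#' Synthetic subjects get ids `<class>_synth_<i>` and are flagged in the
#' logical `synthetic` attribute of the result (original rows are `FALSE`).
#' Output is deterministic given `seed`.
#'
#' @param table a [feature_table()] with >= 2 classes.
#' @param k number of same-class nearest neighbors to draw from
#'   (default 5). Every class that needs synthesis must have more than `k`
#'   members.
#' @param seed integer seed for reproducible synthesis.
#' @return a balanced [feature_table()] with attribute `synthetic`.
#' @export
smote <- function(table, k = 5L, seed = 1L) {
  if (!is.numeric(k) || k < 1L) parameter_error("`k` must be >= 1")
  counts <- base::table(table$label)
  counts <- counts[counts > 0]
  if (length(counts) < 2L)
    parameter_error("SMOTE needs at least two classes")
  target <- max(counts)
  x <- feature_matrix(table)
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  new_rows <- list()
  new_ids <- character(0)
  new_labels <- character(0)
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0L) next
    ridx <- which(table$label == cls)
    if (length(ridx) <= k)
      parameter_error(sprintf(
        "class '%s' has %d members, too few for k = %d neighbors; lower k",
        cls, length(ridx), k))
    zc <- z[ridx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(zc))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
    seeds <- sample(length(ridx), need, replace = TRUE)
    picks <- nn[cbind(seeds, sample(k, need, replace = TRUE))]
    u <- stats::runif(need)
    xs <- x[ridx[seeds], , drop = FALSE]
    xn <- x[ridx[picks], , drop = FALSE]
    synth <- xs + u * (xn - xs)
    new_rows[[cls]] <- synth
    new_ids <- c(new_ids, sprintf("%s_synth_%d", gsub("\\s+", "_", cls),
                                  seq_len(need)))
    new_labels <- c(new_labels, rep(cls, need))
  }
  if (length(new_rows) == 0L) {
    attr(table, "synthetic") <- rep(FALSE, nrow(table))
    return(table)
  }
  add <- do.call(rbind, new_rows)
  colnames(add) <- colnames(x)
  out <- feature_table(rbind(x, add),
                       labels = c(as.character(table$label), new_labels),
                       subject_id = c(table$subject_id, new_ids))
  attr(out, "synthetic") <- c(rep(FALSE, nrow(table)),
                              rep(TRUE, length(new_labels)))
  out
}
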