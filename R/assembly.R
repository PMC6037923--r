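# Assembly of the full radiomic signature: 14 first-order + 8 shape +
# 33 texture + 376 wavelet features = 431 named values per subject, plus
# the subjects-by-features table used for balancing and classification.

HISTOLOGY_CLASSES <- c("adenocarcinoma", "large cell", "squamous cell", "NOS")

#' Canonical radiomic feature names
#'
#' The 431 feature names in extraction order: 14 first-order, 8 shape,
#' 33 texture, then 8 x 47 wavelet features named `<BAND>_<Feature>`.
#'
#' @return character vector of length 431.
#' @export
radiomic_feature_names <- function() {
  wav <- as.vector(vapply(
    WAVELET_BANDS,
    function(b) paste0(b, "_", c(FIRST_ORDER_NAMES, TEXTURE_FEATURE_NAMES)),
    character(47L)))
  c(FIRST_ORDER_NAMES, SHAPE_NAMES, TEXTURE_FEATURE_NAMES, wav)
}

radiomic_feature_blocks <- function() {
  rep(c("firstorder", "shape", "texture", "wavelet"), c(14L, 8L, 33L, 376L))
}

#' Machine-safe column alias for a feature name
#'
#' Replaces whitespace and punctuation with underscores, for CSV headers;
#' [display_name()] inverts the mapping for canonical names.
#'
#' @param name character vector of display names.
#' @return character vector of aliases.
#' @export
feature_alias <- function(name) gsub("[^A-Za-z0-9]+", "_", name)

#' @rdname feature_alias
#' @param alias character vector of aliases.
#' @export
display_name <- function(alias) {
  canon <- c(radiomic_feature_names(), "Compactness")
  map <- stats::setNames(canon, feature_alias(canon))
  out <- unname(map[alias])
  out[is.na(out)] <- alias[is.na(out)]
  out
}

#' Default extraction configuration
#'
#' @param bin_width_hu intensity bin width in Hounsfield units (default 25).
#' @param wavelet_family wavelet filter family, see [wavelet_filters()].
#' @param boundary wavelet boundary extension mode.
#' @param wavelet_bin_policy sub-band discretization policy, see
#'   [wavelet_feature_block()].
#' @param texture_aggregation see [texture_features()].
#' @param glcm_distance co-occurrence displacement in voxels.
#' @param surface_method see [shape_features()].
#' @return a named list of class `extraction_config`.
#' @export
extraction_config <- function(bin_width_hu = 25,
                              wavelet_family = "coif1",
                              boundary = "symmetric",
                              wavelet_bin_policy = "match_level_count",
                              texture_aggregation = "mean_per_direction",
                              glcm_distance = 1L,
                              surface_method = "face_count") {
  cfg <- list(bin_width_hu = bin_width_hu, wavelet_family = wavelet_family,
              boundary = boundary, wavelet_bin_policy = wavelet_bin_policy,
              texture_aggregation = texture_aggregation,
              glcm_distance = glcm_distance, surface_method = surface_method)
  class(cfg) <- "extraction_config"
  cfg
}

config_fingerprint <- function(config) {
  paste(names(config), unlist(config), sep = "=", collapse = ";")
}

#' Extract the full 431-feature radiomic vector
#'
#' Runs the four extraction stages on one image + mask pair and
#' concatenates them in fixed order: 14 first-order features of the masked
#' intensities, 8 shape features of the mask, 33 texture features of the
#' 25-HU discretized region, and 376 wavelet-domain features
#' (14 + 33 per sub-band of the one-level undecimated decomposition).
#' The result is deterministic given the inputs and configuration.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [segmentation_mask()] aligned to `volume`.
#' @param config an [extraction_config()].
#' @param subject_id identifier stored with the vector.
#' @return object of class `feature_vector`: list with `subject_id`,
#'   `values` (named numeric, length 431), `blocks` and `config` (the
#'   configuration fingerprint).
#' @export
extract_all <- function(volume, mask, config = extraction_config(),
                        subject_id = "subject") {
  check_aligned(volume, mask)
  check_nonempty(mask)
  vals <- extract_masked_intensities(volume, mask)
  fo <- first_order_features(vals, config$bin_width_hu)
  sh <- shape_features(mask, surface_method = config$surface_method)
  roi <- discretize(volume, mask, config$bin_width_hu)
  tx <- texture_features(roi, aggregation = config$texture_aggregation,
                         distance = config$glcm_distance)
  wv <- wavelet_feature_block(
    volume, mask, wavelet_filters(config$wavelet_family),
    bin_policy = config$wavelet_bin_policy, bin_width = config$bin_width_hu,
    boundary = config$boundary, aggregation = config$texture_aggregation)
  values <- c(fo, sh, tx, wv)
  stopifnot(length(values) == 431L)
  names(values) <- radiomic_feature_names()
  bad <- names(values)[!is.finite(values)]
  if (length(bad) > 0L)
    extraction_error(paste("non-finite feature value:",
                           paste(bad, collapse = ", ")))
  structure(list(subject_id = subject_id, values = values,
                 blocks = radiomic_feature_blocks(),
                 config = config_fingerprint(config)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> subject ", x$subject_id, ", ",
      length(x$values), " features\n", sep = "")
  invisible(x)
}

# Feature tables ------------------------------------------------------------

#' Build a feature table
#'
#' A `feature_table` is a data frame with a `subject_id` column first, one
#' column per feature (display names) and a `label` column last holding
#' the histology class.
#'
#' @param features numeric matrix or data frame (subjects x features) with
#'   column names, or a list of `feature_vector` objects.
#' @param labels class label per row.
#' @param subject_id optional identifiers (default `S1`, `S2`, ...).
#' @return object of class `feature_table` (a data frame).
#' @export
feature_table <- function(features, labels, subject_id = NULL) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "feature_vector"))) {
    subject_id <- vapply(features, function(f) f$subject_id, character(1))
    features <- do.call(rbind, lapply(features, function(f) f$values))
  }
  features <- as.data.frame(features, check.names = FALSE,
                            optional = TRUE)
  n <- nrow(features)
  if (length(labels) != n)
    schema_error("one label per row is required")
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(n))
  if (anyDuplicated(colnames(features)))
    schema_error("duplicated feature column names")
  lab <- as.character(labels)
  lev <- if (all(lab %in% HISTOLOGY_CLASSES)) HISTOLOGY_CLASSES else sort(unique(lab))
  out <- cbind(data.frame(subject_id = as.character(subject_id),
                          stringsAsFactors = FALSE),
               features,
               data.frame(label = factor(lab, levels = intersect(lev, lab))))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature column names of a table
#' @param table a [feature_table()].
#' @return character vector (everything except `subject_id` and `label`).
#' @export
feature_names <- function(table) {
  setdiff(colnames(table), c("subject_id", "label"))
}

#' Numeric feature matrix of a table
#' @param table a [feature_table()].
#' @return numeric matrix, subjects x features.
#' @export
feature_matrix <- function(table) {
  as.matrix(as.data.frame(table, check.names = FALSE)[, feature_names(table), drop = FALSE])
}

normal_feature_names <- function() c(
  FIRST_ORDER_NAMES,
  "Compactness", "Maximum 3D diameter", "Spherical Disproportion",
  "Sphericity", "Surface Area", "Surface-to-Volume Ratio", "Volume")

#' Restrict a table to the conventional ("normal") feature subset
#'
#' Keeps the 21 conventional features: the 14 first-order statistics plus
#' Compactness, Maximum 3D diameter, Spherical Disproportion, Sphericity,
#' Surface Area, Surface-to-Volume Ratio and Volume. The extractor emits
#' two compactness variants; `Compactness` resolves to `Compactness1`
#' (renamed in the output).
#'
#' @param table a [feature_table()] containing all required columns.
#' @return a [feature_table()] with the 21 conventional feature columns,
#'   rows unchanged.
#' @export
select_normal_subset <- function(table) {
  cols <- colnames(table)
  resolved <- vapply(normal_feature_names(), function(nm) {
    if (nm %in% cols) return(nm)
    if (nm == "Compactness" && "Compactness1" %in% cols) return("Compactness1")
    schema_error(sprintf("required feature column '%s' is missing", nm))
  }, character(1))
  df <- as.data.frame(table, check.names = FALSE)
  out <- df[, c("subject_id", unname(resolved), "label"), drop = FALSE]
  colnames(out) <- c("subject_id", normal_feature_names(), "label")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' One header row with machine-safe column aliases (no spaces),
#' `subject_id` first and `label` last; values round-trip to at least
#' 1e-12 relative precision.
#'
#' @param table a [feature_table()].
#' @param path CSV file path.
#' @return `write_table` returns `path` invisibly; `read_table` returns a
#'   [feature_table()].
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  colnames(df) <- feature_alias(colnames(df))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  if (file.size(path) == 0L) format_error(sprintf("empty CSV file: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) format_error(sprintf("malformed CSV: %s",
                                             conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) < 3L)
    format_error("CSV does not contain a subject/feature/label table")
  if (anyDuplicated(colnames(df)))
    schema_error("duplicated column in CSV header")
  colnames(df) <- display_name(colnames(df))
  if (!all(c("subject_id", "label") %in% colnames(df)))
    schema_error("CSV must contain subject_id and label columns")
  feats <- setdiff(colnames(df), c("subject_id", "label"))
  for (f in feats) df[[f]] <- as.numeric(df[[f]])
  feature_table(df[, feats, drop = FALSE], labels = df$label,
                subject_id = df$subject_id)
}
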