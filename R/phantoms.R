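# Synthetic tumor phantoms and multi-class cohorts. These stand in for a
# clinical CT cohort so every pipeline stage can be exercised and tested
# without downloads: ellipsoidal/cuboidal masks with controllable texture
# (constant, correlated Gaussian field, checkerboard) on small grids, and
# labeled feature cohorts with the skewed four-class sizes typical of an
# NSCLC histology series (40/108/110/59 subjects).

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom specification
#'
#' @param shape grid dimensions, length 3 (default `c(32, 32, 32)`).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param mask_shape `"ellipsoid"`, `"sphere"` or `"cube"`.
#' @param mask_size semi-axes (a, b, c) in voxels for an ellipsoid, radius
#'   for a sphere, edge length for a cube.
#' @param texture `"gaussian_field"`, `"constant"` or `"checkerboard"`.
#' @param texture_params list of texture parameters: `constant`: `value`;
#'   `gaussian_field`: `mean`, `sd`, `correlation` (smoothing length,
#'   voxels); `checkerboard`: `period` (voxels), `levels` (the two values).
#' @param seed integer; fixes the phantom exactly.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                         mask_shape = c("ellipsoid", "sphere", "cube"),
                         mask_size = c(10, 8, 6),
                         texture = c("gaussian_field", "constant", "checkerboard"),
                         texture_params = list(), seed = 1L) {
  mask_shape <- match.arg(mask_shape)
  texture <- match.arg(texture)
  defaults <- switch(texture,
    constant = list(value = 40),
    gaussian_field = list(mean = 40, sd = 150, correlation = 2),
    checkerboard = list(period = 4, levels = c(-50, 100)))
  tp <- utils::modifyList(defaults, texture_params)
  radii <- switch(mask_shape,
    ellipsoid = rep_len(mask_size, 3L),
    sphere = rep(mask_size[1], 3L),
    cube = rep(mask_size[1] / 2, 3L))
  if (any(2 * radii + 1 > shape))
    parameter_error("mask does not fit inside the phantom grid")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 mask_shape = mask_shape, mask_size = mask_size,
                 radii = radii, texture = texture, texture_params = tp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a tumor-like phantom
#'
#' Builds a deterministic (seed-fixed) image volume plus tumor mask from a
#' [phantom_spec()]. The mask is centred in the grid; voxel membership is
#' by centre-inside test, so an ellipsoid with semi-axes (a, b, c) >= 10
#' voxels has a voxel count within a few percent of the continuum volume
#' 4/3 pi a b c.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([voxel_volume()]) and `mask`
#'   ([segmentation_mask()]).
#' @export
make_phantom <- function(spec) {
  d <- spec$shape
  centre <- (d + 1) / 2
  xi <- (seq_len(d[1]) - centre[1])
  yi <- (seq_len(d[2]) - centre[2])
  zi <- (seq_len(d[3]) - centre[3])
  mask <- switch(spec$mask_shape,
    cube = {
      half <- spec$mask_size[1] / 2
      outer(outer(abs(xi) <= half, abs(yi) <= half, "&"), abs(zi) <= half, "&")
    },
    { # sphere / ellipsoid: centre-inside quadric test
      r <- spec$radii
      q <- outer(outer((xi / r[1])^2, (yi / r[2])^2, "+"), (zi / r[3])^2, "+")
      q <= 1
    })
  tp <- spec$texture_params
  data <- with_seed(spec$seed, switch(spec$texture,
    constant = array(tp$value, dim = d),
    checkerboard = {
      cell <- outer(outer(xi %/% tp$period, yi %/% tp$period, "+"),
                    zi %/% tp$period, "+")
      array(tp$levels[(cell %% 2) + 1], dim = d)
    },
    gaussian_field = {
      noise <- array(stats::rnorm(prod(d)), dim = d)
      if (tp$correlation > 0) {
        k <- gaussian_kernel(tp$correlation)
        for (axis in 1:3) noise <- correlate_axis(noise, k, axis, "symmetric")
      }
      noise <- (noise - mean(noise)) / stats::sd(noise)
      tp$mean + tp$sd * noise
    }))
  list(volume = voxel_volume(data, spacing = spec$spacing),
       mask = segmentation_mask(mask, spacing = spec$spacing))
}

#' Cohort specification
#'
#' @param class_sizes named or unnamed integer vector of subjects per
#'   class; the default 40/108/110/59 mirrors the skew of a typical NSCLC
#'   histology series (adenocarcinoma / large cell / squamous cell / NOS).
#' @param mode `"features"`: sample the 431-dimensional feature vectors
#'   directly (fast; for modeling studies); `"images"`: generate a phantom
#'   per subject and run [extract_all()] (slow; exercises extraction
#'   end-to-end).
#' @param effect_size mean shift, in within-class standard deviations,
#'   applied to the signal columns of each class (features mode), or the
#'   scale of per-class texture/shape parameter offsets (images mode).
#'   0 gives an exchangeable (null) cohort.
#' @param signal_features feature names carrying class signal in features
#'   mode. The default places all signal in wavelet-texture columns, the
#'   regime where the radiomic signature has information the conventional
#'   21-feature subset lacks.
#' @param n_features number of feature columns in features mode; the
#'   default keeps the full 431-name signature.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(class_sizes = c(adenocarcinoma = 40L,
                                        `large cell` = 108L,
                                        `squamous cell` = 110L,
                                        NOS = 59L),
                        mode = c("features", "images"),
                        effect_size = 2,
                        signal_features = NULL,
                        n_features = NULL,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (any(class_sizes < 1L)) parameter_error("class sizes must be >= 1")
  if (is.null(names(class_sizes)))
    names(class_sizes) <- HISTOLOGY_CLASSES[seq_along(class_sizes)]
  structure(list(class_sizes = class_sizes, mode = mode,
                 effect_size = effect_size,
                 signal_features = signal_features,
                 n_features = n_features, seed = as.integer(seed)),
            class = "cohort_spec")
}

default_signal_features <- function() {
  # wavelet-domain texture columns: sub-band GLCM/GLRLM features
  nm <- radiomic_feature_names()
  wav_tex <- nm[grepl("^(LLH|LHL|LHH|HLL|HLH|HHL|HHH)_", nm) &
                  grepl("Entropy|Contrast|Emphasis|Autocorrelation", nm)]
  wav_tex
}

#' Generate a labeled multi-class cohort
#'
#' In `"features"` mode each subject's feature vector is drawn from a
#' class-conditional Gaussian: unit-variance noise in every column, plus a
#' class-specific mean shift of `effect_size` standard deviations on the
#' signal columns (a distinct +/- sign pattern per class, so all four
#' classes are mutually separated). In `"images"` mode each subject is a
#' textured ellipsoid phantom whose texture contrast and shape are offset
#' per class, passed through [extract_all()].
#'
#' @param spec a [cohort_spec()].
#' @param config an [extraction_config()] (images mode only).
#' @return a [feature_table()] with the requested class sizes.
#' @export
make_cohort <- function(spec, config = extraction_config()) {
  sizes <- spec$class_sizes
  labels <- rep(names(sizes), times = sizes)
  if (spec$mode == "features") {
    nm <- if (!is.null(spec$n_features))
      paste0("F", seq_len(spec$n_features)) else radiomic_feature_names()
    signal <- spec$signal_features
    if (is.null(signal)) {
      signal <- if (is.null(spec$n_features)) default_signal_features()
        else nm[seq_len(min(5L, length(nm)))]
    }
    sig_idx <- match(signal, nm)
    if (anyNA(sig_idx)) parameter_error("unknown signal feature name")
    n <- sum(sizes)
    p <- length(nm)
    with_seed(spec$seed, {
      x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nm))
      # orthogonal-ish sign patterns, one per class
      patterns <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
      for (ci in seq_along(sizes)) {
        rows <- which(labels == names(sizes)[ci])
        half <- ceiling(length(sig_idx) / 2)
        shift <- rep(patterns[1 + (ci - 1) %% 4, ], c(half, length(sig_idx) - half))
        x[rows, sig_idx] <- x[rows, sig_idx] +
          matrix(spec$effect_size * shift, length(rows), length(sig_idx),
                 byrow = TRUE)
      }
      feature_table(x, labels = labels)
    })
  } else {
    n <- sum(sizes)
    with_seed(spec$seed, {
      subject_seeds <- sample.int(1e6, n)
      vecs <- vector("list", n)
      for (i in seq_len(n)) {
        ci <- match(labels[i], names(sizes))
        off <- spec$effect_size * (ci - 1)
        ps <- phantom_spec(
          shape = c(24L, 24L, 24L),
          mask_size = pmin(10.5, pmax(4, c(8, 7, 6) + stats::rnorm(3, sd = 0.5) + 0.4 * off)),
          texture = "gaussian_field",
          texture_params = list(mean = 40 + 15 * off, sd = 120 + 25 * off,
                                correlation = 1.5 + 0.3 * off),
          seed = subject_seeds[i])
        ph <- make_phantom(ps)
        vecs[[i]] <- extract_all(ph$volume, ph$mask, config,
                                 subject_id = sprintf("P%03d", i))
      }
      feature_table(vecs, labels = labels)
    })
  }
}
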