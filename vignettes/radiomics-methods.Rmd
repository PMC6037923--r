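---
title: "Methods: radiomic feature extraction and histology classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic feature extraction and histology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`ctradiomics` implements a complete CT radiomics pipeline for
non–small cell lung cancer (NSCLC) histology classification: a tumor
region delineated on a CT volume (the gross tumor volume, GTV) is
summarized by a fixed 431-feature signature — 14 first-order intensity
statistics, 8 shape and size features, 33 gray-level co-occurrence
(GLCM) and run-length (GLRLM) texture features, and 376 features from a
one-level undecimated 3-D wavelet decomposition (14 + 33 per sub-band
times 8 sub-bands). Signatures from a cohort are balanced with SMOTE and
classified into the four histology classes (adenocarcinoma, large cell,
squamous cell, NOS) by a 10-fold cross-validated multiclass RBF-SVM,
with filter-style feature ranking and a paired comparison against a
21-feature "conventional" model (first-order plus shape only).

This vignette records the modelling conventions, the tunable parameters,
the numerical choices made where the design was genuinely open, and what
the synthetic phantoms do and do not establish about clinical data.

# Geometry and input handling

Volumes are kept on their native voxel lattice — no resampling,
reorientation or intensity normalization is applied. Arrays are ordered
(x, y, z); physical position of 1-based index `(i, j, k)` is
`origin + (i-1, j-1, k-1) * spacing` (mm). DICOM series are sorted by
slice position along the normal, rescaled to Hounsfield units (HU) with
the stored slope/intercept, and rejected if slice gaps deviate by more
than 1 % of the median spacing (a missing slice is a geometry error, not
something to interpolate over). Only axis-aligned axial series are
accepted; registration between mismatched grids is out of scope.

RTSTRUCT contours are rasterized with the even-odd (parity) rule on
voxel centres, applied half-open in the standard scanline fashion: a
centre on the left/bottom polygon boundary is inside, on the right/top
boundary outside. This tie-break is deterministic and adjacency-safe
(two abutting contours never both claim a centre): a 10 mm × 10 mm
square contour on a 1 mm grid anchored at the origin covers exactly the
100 centres at 0–9 mm. Multiple polygons on one slice combine by
parity, so ring-shaped structures produce holes. A contour must lie
within half a slice spacing of a grid slice.

# Discretization

Masked intensities are re-coded into equally spaced bins of width 25 HU
(configurable, `bin_width_hu`), anchored at the masked minimum:
`level(x) = floor((x - min) / w) + 1`. Min-anchoring makes the coding
invariant to adding a constant to all intensities, and the maximum falls
in the top bin without clipping. The same histogram feeds the
first-order Entropy and Uniformity features, so those two are also
computed on the binned distribution.

Wavelet sub-band values are not Hounsfield units, so the 25-HU width
does not transfer. Each sub-band is discretized with its own
min-anchored bins under the `wavelet_bin_policy` configuration:
`match_level_count` (default) chooses the width so the sub-band gets the
same number of gray levels as the original image — keeping texture
matrices comparable in size across bands — while `fixed_width` reuses
the original width unchanged. A constant sub-band (e.g. any high-pass
band of a constant image) degenerates to a single level.

# Feature definitions

**First-order (14).** Energy, Entropy, Kurtosis, Maximum, Mean, Mean
Absolute Deviation, Median, Minimum, Range, RMS Value, Skewness,
Standard Deviation, Uniformity, Variance. Moments are population (1/N)
moments and kurtosis is the non-excess Pearson form (a large normal
sample scores about 3), following the radiomics convention of the
framework this signature family derives from. Skewness and kurtosis of
a constant region are defined as 0 rather than NaN so that feature
vectors stay finite. Entropy uses base-2 logarithms; empty bins
contribute zero.

**Shape (8).** Volume V is voxel count times voxel volume. Two surface
area estimators are available (`surface_method`):

* `face_count` (default): the summed area of mask faces exposed to the
  outside. Exact for axis-aligned solids (a 10³ cube at 1 mm gives
  exactly A = 600 mm²), but it overestimates curved surfaces — the
  staircase area of a digitized ball tends to 3/2 of the smooth area no
  matter how fine the grid.
* `gradient`: integrates the gradient magnitude of a Gaussian-smoothed
  indicator function (a co-area / stereological estimator). The
  bandwidth, 0.6 × max spacing, was calibrated on analytic balls: area
  bias stays under about 1.5 % for radii ≥ 6 voxels and digitized-ball
  sphericity stays at or just below 1. Prefer it for smooth blob-like
  tumors; it rounds sharp edges. (A triangulated mesh was considered
  and rejected: a marching-cubes mesh on binary data plateaus at ball
  sphericity ≈ 0.92 and does not converge to the analytic limit.)

From V and A: sphericity = π^{1/3}(6V)^{2/3}/A, compactness1 =
V/(√π A^{3/2}), compactness2 = 36πV²/A³, spherical disproportion =
A/(4πR²) with R the volume-equivalent radius, and surface-to-volume
ratio A/V. The identities compactness2 = sphericity³ and
disproportion × sphericity = 1 hold by construction and are asserted in
tests. Maximum 3D diameter is the largest Euclidean distance between
surface-voxel centres (surface voxels suffice: the diameter endpoints
of a finite voxel set are always exposed). Both compactness variants
are emitted — the conventional single "Compactness" name resolves to
compactness1 — bringing the shape block to its documented count of 8.

**Texture (33).** GLCMs and GLRLMs are built over the 13 unique
directions of the 26-neighborhood (one per antipodal pair) at a
displacement of one voxel in index space; grid anisotropy is
deliberately ignored in the offsets, matching the native-lattice policy
above. GLCM pairs require both endpoints inside the mask and are
counted symmetrically. GLRLM runs are maximal same-level segments along
a direction and terminate at the mask boundary. Features — 22
co-occurrence (Haralick-style, plus GLCM Variance) and 11 run-length —
are computed per direction and averaged with equal weight
(`texture_aggregation = "mean_per_direction"`); pooling matrices across
directions before one feature computation is available as `"merged"`.
Conventions worth stating:

* Sum Variance is taken about the Sum Average (the modern reading of
  the classical definition).
* Correlation and both informational measures of correlation are
  defined as 0 on zero-variance (single-level) matrices, and Inverse
  Variance sums only off-diagonal terms, so all 33 features are finite
  on every non-empty region.
* Three co-occurrence features would collide with first-order names
  (Energy, Entropy, Variance); they are exported as `GLCM Energy`,
  `GLCM Entropy`, `GLCM Variance`. A ranked feature printed as
  `LHL_Entropy` therefore refers to the first-order entropy of the LHL
  sub-band.
* A direction with no valid pair yields an all-zero matrix that is
  flagged and excluded from the average.

**Wavelet (376).** One level of an undecimated (stationary) separable
decomposition into 8 sub-bands named LLL … HHH, the first letter
filtering x, the second y, the third z (X_HLH = high-pass x, low-pass
y, high-pass z; where a source's displayed equation and its prose
conflict on this convention, the prose convention is followed). Filters
are applied by centred correlation — `out(i) = Σ_p k[p] x(i + p - 1 - c)`
with `c = floor((N-1)/2)` — with symmetric (mirror) boundary extension
by default, so results are bit-reproducible. The default family is
Coiflet-1, with Haar available for exact hand-checkable tests. Because
the transform is undecimated it is redundant: with orthonormal filters
|L(ω)|² + |H(ω)|² = 2 per axis, so the 8 sub-band energies of an
interior-supported signal sum to exactly 8× the signal energy (the
tested invariant). Each sub-band, restricted to the same mask, yields
the 14 first-order and 33 texture features, named `<BAND>_<Feature>`.

# Balancing and classification

**SMOTE.** Each minority class is grown to the majority count.
Synthetic points are `s = x + u (x_nn − x)` with `u ~ U(0, 1)` and
`x_nn` one of the k = 5 nearest same-class neighbors (Euclidean
distance on globally standardized features; interpolation in the
original space). Original rows pass through untouched; synthesis is
deterministic given a seed. Within cross-validation SMOTE is applied
inside each training fold only — never to held-out rows — because
oversampling before splitting leaks synthetic copies of test
information into training; whole-dataset balancing remains available by
calling `smote()` directly before `cross_validate()`.

**SVM.** Multiclass C-classification with an RBF kernel via e1071
(libsvm), one-vs-one with majority voting by default (one-vs-rest via
`decomposition`). Defaults follow the grid-searched clinical operating
point: gamma 1.0, C 0.1, termination tolerance 1e-4 — the quoted
"epsilon 1e-4" is interpreted as the optimizer tolerance, since an
epsilon-tube is meaningless for classification. Features are
z-standardized with training-fold statistics. A caveat the package makes
explicit: a fixed gamma of 1.0 encodes the scale of the dataset it was
tuned on; on feature sets of very different dimension the RBF distances
grow with p and the kernel saturates. `svm_params(gamma = NULL)`
requests the standard 1/p scaling instead, and is what the synthetic
model-comparison experiments use, since they put 431-dimensional and
21-dimensional models side by side.

**Metrics.** Held-out predictions are pooled into one 4×4 confusion
matrix (fold-order invariant). Per-class sensitivity TP/(TP+FN) and
specificity TN/(TN+FP) are reported one-vs-rest, with both macro
(unweighted class mean) and micro (pooled counts) averages, since a
single summary number for a 4-class task is ambiguous; accuracy is the
trace over n.

**Ranking.** Feature importance is filter-style: the maximum over
classes of the orientation-free one-vs-rest ROC area of the single
feature, scaled to 0–100, ties broken by name. This is deliberately
model-agnostic — importances extracted from a nonlinear SVM are not
well defined — and a perfectly class-aligned feature scores 100 and
ranks first.

**Model comparison.** `compare_models()` cross-validates the full
431-feature table and its 21-feature conventional subset on identical
fold assignments and tests the paired held-out correctness indicators
with a continuity-corrected McNemar test, (|b−c|−1)²/(b+c) against
χ²₁; no discordant pairs gives p = 1.

# Synthetic phantoms and cohorts

`make_phantom()` builds seed-deterministic masked volumes: ellipsoid,
sphere or cube masks (centre-inside test; a digitized ellipsoid with
radii ≥ 10 voxels is within a few percent of 4/3 πabc) with constant,
checkerboard or correlated Gaussian-field texture. The Gaussian field
defaults (mean 40 HU, SD 150 HU, correlation length 2 voxels) give
soft-tissue-like values spanning several dozen 25-HU bins on a 32³
grid — enough structure for every texture matrix to be non-degenerate.

`make_cohort()` produces labeled cohorts in two modes. The default
class sizes 40/108/110/59 mirror the skew of a typical NSCLC histology
series. *Feature mode* samples 431-dimensional Gaussians: unit noise
everywhere plus a class-specific ±effect-size mean shift (a distinct
sign pattern per class) on a configurable signal column set, which
defaults to wavelet-domain texture-type columns — the regime where the
radiomic signature carries information the 21 conventional features
cannot see. The default effect size of 2 within-class standard
deviations is a moderate, realistic radiomic separation. *Image mode*
generates a textured ellipsoid phantom per subject (24³ grid; texture
contrast and shape offset per class) and runs the full extractor; it
exercises extraction end to end and is kept for small n, while feature
mode keeps modelling studies at desk-scale runtimes (the test suite
uses cohorts of 200–400 subjects in feature mode and 8 in image mode).

What passing these tests shows: the extraction arithmetic is correct to
oracle precision, the pipeline's contracts hold, and the modelling
stack detects class structure it should detect and nothing when there
is none. What it does not show: clinical performance. The phantoms have
no CT physics (no beam hardening, no noise spectra, no partial-volume
mixtures), their class differences are put in by construction, and no
claim about real histology discrimination follows from them.

# Numerical and degenerate-input conventions

* Geometry equality tolerance 1e-3 mm; contour-to-slice matching
  tolerance half a slice spacing; round-trips preserve geometry to 1e-6.
* Empty masks raise an empty-ROI error everywhere; a non-finite feature
  aborts extraction naming the offending feature.
* Bins, runs and pairs are integer computations on the discretized
  grid, so extraction is bit-reproducible for identical inputs and
  configuration; the configuration fingerprint is stored with every
  feature vector.
* Filter kernels longer than a (padded) dimension are a parameter
  error; Gaussian smoothing kernels are truncated at 3σ and capped at
  the dimension size.
* Fold assignment, SMOTE and cohort synthesis consume seeds through a
  scoped RNG that restores the caller's random state.

# Known limitations

* No automated tumor segmentation: masks come from provided contours or
  label volumes by design.
* No image registration or resampling; mismatched grids are an error.
* DICOM support covers uncompressed little-endian CT series and
  RTSTRUCT objects — the subset used by archived CT studies.
* No clinical performance figures are claimed: reproducing them would
  require an external patient cohort. The package reproduces the
  method, and its synthetic experiments demonstrate the
  radiomic-over-conventional advantage qualitatively.
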