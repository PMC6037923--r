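Package: ctradiomics
Title: CT Radiomics for Tumor Histology Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image feature extraction and classification for
    computed-tomography tumor studies. Reads CT volumes (DICOM series, NIfTI,
    NRRD) and tumor delineations (DICOM-RTSTRUCT contours or label masks),
    extracts a named 431-feature radiomic signature per subject (14 first-order
    statistics, 8 shape and size features, 33 gray-level co-occurrence and
    run-length texture features, and 376 features from a one-level undecimated
    3-D wavelet decomposition), balances skewed histology classes with SMOTE,
    and classifies with a 10-fold cross-validated multiclass RBF support vector
    machine, including feature ranking and a radiomic-versus-conventional model
    comparison. Ships a deterministic synthetic phantom and cohort generator so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
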