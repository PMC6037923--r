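# Volume file IO: NIfTI via RNifti, NRRD via a small native reader/writer.
# Grids are kept on the native voxel lattice; no resampling or reorientation
# is performed (axes are assumed aligned with the patient x/y/z axes).

#' Read a CT image volume
#'
#' Reads a 3-D scalar volume from a DICOM series directory, a NIfTI file or
#' an NRRD file into a [voxel_volume()]. DICOM slices are sorted by their
#' position along the slice normal and rescaled to Hounsfield units with the
#' stored slope/intercept.
#'
#' @param path file (NIfTI/NRRD) or directory (DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"nrrd"`, `"dicom-series"`.
#'   `"auto"` picks by extension (directory implies DICOM).
#' @return A [voxel_volume()].
#' @export
read_image_volume <- function(path,
                              format = c("auto", "nifti", "nrrd", "dicom-series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    format_error(sprintf("path does not exist: %s", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom-series"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else format_error(sprintf("cannot infer volume format of %s", path))
  }
  switch(format,
    "nifti" = read_nifti_volume(path),
    "nrrd" = read_nrrd_volume(path),
    "dicom-series" = read_dicom_series(path))
}

#' Write a volume to NIfTI or NRRD
#'
#' @param volume a [voxel_volume()] or [segmentation_mask()] (written as
#'   0/1 integers).
#' @param path output file; extension selects the format (`.nii`,
#'   `.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(volume, path) {
  data <- volume$data
  if (is.logical(data)) {
    data <- array(as.double(data), dim = dim(data))
  }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_volume(data, volume$spacing, volume$origin, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- volume$spacing
    m <- diag(c(volume$spacing, 1))
    m[1:3, 4] <- volume$origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    format_error(sprintf("unsupported output extension for %s", path))
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) format_error(
                    sprintf("unreadable NIfTI file %s: %s", path, conditionMessage(e))))
  a <- array(as.double(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    geometry_error("NIfTI volume is not 3-D")
  spacing <- abs(RNifti::pixdim(img)[1:3])
  xf <- RNifti::xform(img)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  voxel_volume(a, spacing = spacing, origin = origin)
}

#' Read a label mask volume aligned to a reference image
#'
#' Nonzero voxels become mask voxels. The mask grid must match the
#' reference geometry (shape exactly; spacing/origin within 1e-3 mm).
#'
#' @param path NIfTI or NRRD mask file.
#' @param reference the [voxel_volume()] the mask annotates.
#' @return A [segmentation_mask()].
#' @export
read_mask_volume <- function(path, reference) {
  v <- read_image_volume(path)
  if (!identical(dim(v$data), dim(reference$data)))
    geometry_error("mask shape does not match reference volume")
  if (max(abs(v$spacing - reference$spacing)) > 1e-3 ||
      max(abs(v$origin - reference$origin)) > 1e-3)
    geometry_error("mask geometry does not match reference volume")
  segmentation_mask(v$data != 0, spacing = reference$spacing,
                    origin = reference$origin)
}

# NRRD ----------------------------------------------------------------------
# Minimal NRRD4 support: attached data, raw/gzip/ascii encodings, little
# endian, 3-D scalar grids.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE))

parse_nrrd_vector <- function(txt) {
  txt <- gsub("[()]", "", trimws(txt))
  as.numeric(strsplit(txt, ",")[[1]])
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic))
    format_error(sprintf("%s is not an NRRD file", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L)
      format_error("NRRD header ended without a data section")
    if (line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) next  # key-value metadata, ignored
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) format_error(sprintf("malformed NRRD field: %s", line))
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  if (is.null(fields$sizes) || is.null(fields$type))
    format_error("NRRD header missing `sizes` or `type`")
  sizes <- as.integer(strsplit(fields$sizes, "[ \t]+")[[1]])
  if (length(sizes) != 3L)
    geometry_error("only 3-D NRRD volumes are supported")
  tp <- nrrd_types[[fields$type]]
  if (is.null(tp))
    format_error(sprintf("unsupported NRRD type: %s", fields$type))
  if (!is.null(fields$endian) && fields$endian == "big")
    format_error("big-endian NRRD data is not supported")
  enc <- if (is.null(fields$encoding)) "raw" else fields$encoding
  n <- prod(sizes)
  vals <- switch(enc,
    "raw" = readBin(con, tp$what, n = n, size = tp$size,
                    signed = tp$signed, endian = "little"),
    "gzip" = , "gz" = {
      gz <- gzcon(con)
      readBin(gz, tp$what, n = n, size = tp$size,
              signed = tp$signed, endian = "little")
    },
    "ascii" = , "txt" = , "text" = scan(con, what = double(), n = n, quiet = TRUE),
    format_error(sprintf("unsupported NRRD encoding: %s", enc)))
  if (length(vals) != n)
    format_error("NRRD data section shorter than the declared sizes")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    if (length(dirs) == 3L) {
      mat <- vapply(dirs, parse_nrrd_vector, numeric(3))
      spacing <- sqrt(colSums(mat^2))
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- abs(as.numeric(strsplit(fields$spacings, "[ \t]+")[[1]]))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vector(fields[["space origin"]])
  # NRRD lists sizes fastest-axis first, matching R's column-major layout
  voxel_volume(array(as.double(vals), dim = sizes),
               spacing = spacing, origin = origin)
}

write_nrrd_volume <- function(data, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by ctradiomics",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            origin[1], origin[2], origin[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}
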