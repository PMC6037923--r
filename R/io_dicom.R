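# Minimal native DICOM reader, covering what CT radiomics needs: CT image
# series (uncompressed, explicit or implicit VR little endian) and
# RTSTRUCT contour sets. No R DICOM parser is depended upon; the format
# subset handled here is the part-10 little-endian encoding used by
# archived CT studies. Compressed transfer syntaxes are rejected.

DCM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  # returned as double: 0xFFFFFFFF (undefined length) overflows R integers
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
# tags parsed as sequences under implicit VR
DCM_SQ_TAGS <- c("30060020", "30060039", "30060040", "30060080", "30060010",
                 "30060012", "30060014", "30060016", "00081115", "00081140")

dcm_tag <- function(group, elem) sprintf("%04X%04X", group, elem)

# Parse one dataset stretch [pos, end]; returns list(elements, pos).
# Elements: named list tag -> list(vr, bytes) or list(vr = "SQ", items).
dcm_parse_dataset <- function(raw, pos, end, explicit, stop_tag = NULL) {
  elements <- list()
  while (pos + 7 <= end) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    tag <- dcm_tag(group, elem)
    if (!is.null(stop_tag) && tag == stop_tag) {
      pos <- pos + 8L  # consume delimiter tag + zero length
      break
    }
    pos <- pos + 4L
    vr <- NA_character_
    if (group == 0xFFFEL) {
      len <- dcm_u32(raw, pos); pos <- pos + 4L
    } else if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)]); pos <- pos + 2L
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(raw, pos + 2L); pos <- pos + 6L
      } else {
        len <- as.numeric(dcm_u16(raw, pos)); pos <- pos + 2L
      }
    } else {
      len <- dcm_u32(raw, pos); pos <- pos + 4L
      if (tag %in% DCM_SQ_TAGS) vr <- "SQ"
    }
    undefined <- len == 4294967295
    is_seq <- identical(vr, "SQ") || (undefined && group != 0x7FE0L)
    if (is_seq) {
      item_end <- if (undefined) end else pos + len - 1
      items <- list()
      while (pos + 7 <= item_end) {
        ig <- dcm_u16(raw, pos); ie <- dcm_u16(raw, pos + 2L)
        if (ig == 0xFFFEL && ie == 0xE0DDL) { pos <- pos + 8L; break }
        if (!(ig == 0xFFFEL && ie == 0xE000L))
          format_error("malformed DICOM sequence: expected item tag")
        ilen <- dcm_u32(raw, pos + 4L); pos <- pos + 8L
        if (ilen == 4294967295) {
          parsed <- dcm_parse_dataset(raw, pos, item_end, explicit,
                                      stop_tag = "FFFEE00D")
        } else {
          parsed <- dcm_parse_dataset(raw, pos, pos + ilen - 1, explicit)
        }
        items[[length(items) + 1L]] <- parsed$elements
        pos <- parsed$pos
      }
      elements[[tag]] <- list(vr = "SQ", items = items)
    } else {
      if (undefined)
        format_error("undefined-length pixel data (compressed syntax?) not supported")
      bytes <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
      elements[[tag]] <- list(vr = vr, bytes = bytes)
      pos <- pos + len
    }
  }
  list(elements = elements, pos = pos)
}

# Parse a part-10 DICOM file into its element list plus transfer syntax.
dcm_parse_file <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n = n)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    format_error(sprintf("%s is not a part-10 DICOM file", path))
  pos <- 133
  # file meta group (0002) is always explicit VR little endian
  meta <- list()
  while (pos + 7 <= n) {
    if (dcm_u16(raw, pos) != 0x0002L) break
    elem <- dcm_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_u32(raw, pos + 8L); hdr <- 12L
    } else {
      len <- as.numeric(dcm_u16(raw, pos + 6L)); hdr <- 8L
    }
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1)] else raw(0)
    meta[[dcm_tag(0x0002L, elem)]] <- list(vr = vr, bytes = val)
    pos <- pos + hdr + len
  }
  ts <- dcm_string(meta, "00020010")
  if (is.null(ts)) ts <- DCM_EXPLICIT_LE
  if (!ts %in% c(DCM_IMPLICIT_LE, DCM_EXPLICIT_LE))
    format_error(sprintf("unsupported DICOM transfer syntax %s", ts))
  parsed <- dcm_parse_dataset(raw, pos, n, explicit = ts == DCM_EXPLICIT_LE)
  list(elements = c(meta, parsed$elements), transfer_syntax = ts)
}

dcm_string <- function(elements, tag) {
  el <- elements[[tag]]
  if (is.null(el)) return(NULL)
  sub("[\\s\\0]+$", "", rawToChar(el$bytes), perl = TRUE)
}

dcm_numeric <- function(elements, tag) {
  s <- dcm_string(elements, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16_value <- function(elements, tag) {
  el <- elements[[tag]]
  if (is.null(el)) return(NULL)
  dcm_u16(el$bytes, 1L)
}

# CT series -----------------------------------------------------------------

read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    format_error(sprintf("no files in DICOM directory %s", path))
  slices <- list()
  for (f in files) {
    parsed <- tryCatch(dcm_parse_file(f), error = function(e) NULL)
    if (is.null(parsed)) next
    el <- parsed$elements
    if (is.null(el[["7FE00010"]])) next  # not an image object
    slices[[length(slices) + 1L]] <- list(file = f, elements = el)
  }
  if (length(slices) == 0L)
    format_error(sprintf("no readable DICOM image slices in %s", path))

  first <- slices[[1L]]$elements
  iop <- dcm_numeric(first, "00200037")
  if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-3)
    geometry_error("only axis-aligned axial DICOM series are supported")
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])

  pos_along <- vapply(slices, function(s) {
    ipp <- dcm_numeric(s$elements, "00200032")
    if (is.null(ipp)) geometry_error("DICOM slice lacks ImagePositionPatient")
    sum(ipp * normal)
  }, numeric(1))
  ord <- order(pos_along)
  slices <- slices[ord]
  pos_along <- pos_along[ord]

  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(pos_along)
    dz <- stats::median(gaps)
    if (dz <= 0 || any(abs(gaps - dz) > 0.01 * dz + 1e-3))
      geometry_error("inconsistent DICOM slice spacing (missing slice?)")
  } else dz <- 1
  pixsp <- dcm_numeric(first, "00280030")  # (row spacing = dy, col spacing = dx)
  if (is.null(pixsp)) pixsp <- c(1, 1)
  rows <- dcm_uint16_value(first, "00280010")
  cols <- dcm_uint16_value(first, "00280011")

  vol <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    el <- slices[[k]]$elements
    bits <- dcm_uint16_value(el, "00280100"); if (is.null(bits)) bits <- 16L
    signed <- identical(dcm_uint16_value(el, "00280103"), 1L)
    slope <- dcm_numeric(el, "00281053"); if (is.null(slope)) slope <- 1
    inter <- dcm_numeric(el, "00281052"); if (is.null(inter)) inter <- 0
    bytes <- el[["7FE00010"]]$bytes
    stored <- readBin(bytes, "integer", n = rows * cols,
                      size = bits %/% 8L, signed = signed || bits > 16L,
                      endian = "little")
    if (length(stored) != rows * cols)
      format_error(sprintf("truncated pixel data in %s", slices[[k]]$file))
    # DICOM pixel data is row-major: the first `cols` values form row 1
    vol[, , k] <- matrix(stored, nrow = cols, ncol = rows) * slope + inter
  }
  ipp0 <- dcm_numeric(slices[[1L]]$elements, "00200032")
  voxel_volume(vol, spacing = c(pixsp[2], pixsp[1], dz), origin = ipp0)
}

# RTSTRUCT ------------------------------------------------------------------

#' Read a DICOM-RTSTRUCT contour set
#'
#' Extracts the planar contours of every region of interest in a
#' radiotherapy structure-set file as a [contour_set()] in physical
#' coordinates (mm).
#'
#' @param path an RTSTRUCT DICOM file.
#' @return A [contour_set()].
#' @export
read_rtstruct <- function(path) {
  if (!file.exists(path)) format_error(sprintf("path does not exist: %s", path))
  el <- dcm_parse_file(path)$elements
  ssr <- el[["30060020"]]  # StructureSetROISequence
  rcs <- el[["30060039"]]  # ROIContourSequence
  if (is.null(rcs))
    format_error("file has no ROIContourSequence; not an RTSTRUCT?")
  roi_names <- list()
  if (!is.null(ssr)) {
    for (item in ssr$items) {
      num <- dcm_string(item, "30060022")
      nm <- dcm_string(item, "30060026")
      if (!is.null(num) && !is.null(nm)) roi_names[[num]] <- nm
    }
  }
  contours <- list()
  for (item in rcs$items) {
    ref <- dcm_string(item, "30060084")
    nm <- if (!is.null(ref) && !is.null(roi_names[[ref]])) roi_names[[ref]]
      else paste0("ROI-", ref)
    cs <- item[["30060040"]]  # ContourSequence
    if (is.null(cs)) next
    for (ct in cs$items) {
      xyz <- dcm_numeric(ct, "30060050")  # ContourData
      if (is.null(xyz) || length(xyz) < 9L) next
      pts <- matrix(xyz, ncol = 3L, byrow = TRUE)
      contours[[length(contours) + 1L]] <- list(
        roi = nm, z = mean(pts[, 3L]), vertices = pts[, 1:2, drop = FALSE])
    }
  }
  if (length(contours) == 0L)
    format_error("RTSTRUCT contains no planar contours")
  contour_set(contours)
}
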