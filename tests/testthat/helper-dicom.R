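# Minimal explicit-VR little-endian DICOM writer, used only to build
# fixtures at test time (the deliverable carries no binary files).

.u16raw <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# one explicit-VR data element
dcm_element <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    US = .u16raw(value),
    UL = .u32raw(value),
    OW = value,  # already raw
    OB = value,
    UI = .pad_even(charToRaw(value), as.raw(0)),
    .pad_even(charToRaw(value)))  # DS/IS/LO/CS/SH...
  head <- c(.u16raw(group), .u16raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32raw(length(bytes)), bytes)
  } else {
    c(head, .u16raw(length(bytes)), bytes)
  }
}

# sequence element with defined-length items; items = list of raw vectors
dcm_sequence <- function(group, elem, items) {
  body <- raw(0)
  for (it in items)
    body <- c(body, .u16raw(0xFFFE), .u16raw(0xE000), .u32raw(length(it)), it)
  c(.u16raw(group), .u16raw(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    .u32raw(length(body)), body)
}

dcm_preamble_meta <- function(sop_class, sop_instance) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  c(raw(128), charToRaw("DICM"), meta)
}

# write one CT slice; stored is an integer matrix indexed [x, y]
write_ct_slice <- function(path, stored, ipp, pixel_spacing = c(1, 1),
                           slope = 1, intercept = -1024, uid_suffix = "1") {
  cols <- nrow(stored)  # x
  rows <- ncol(stored)  # y
  pix <- writeBin(as.integer(as.vector(stored)), raw(), size = 2,
                  endian = "little")
  ds <- function(v) paste(sprintf("%.6g", v), collapse = "\\")
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", paste0("1.2.826.0.1.99999.1.", uid_suffix)),
    dcm_element(0x0020, 0x0032, "DS", ds(ipp)),
    dcm_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0010, "US", rows),
    dcm_element(0x0028, 0x0011, "US", cols),
    dcm_element(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", 1),
    dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(dcm_preamble_meta("1.2.840.10008.5.1.4.1.1.2",
                               paste0("1.2.826.0.1.99999.1.", uid_suffix)),
             body), path)
  invisible(path)
}

# write a small axial DICOM series of a volume [x, y, z] of stored values
write_dicom_series <- function(dir, stored_vol, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), slope = 1,
                               intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(stored_vol)[3]
  for (k in seq_len(nz)) {
    write_ct_slice(
      file.path(dir, sprintf("slice%03d.dcm", k)),
      stored_vol[, , k],
      ipp = c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3]),
      pixel_spacing = c(spacing[2], spacing[1]),  # (row, col) = (dy, dx)
      slope = slope, intercept = intercept, uid_suffix = as.character(k))
  }
  invisible(dir)
}

# write an RTSTRUCT with the given contours (list of list(roi, z, vertices))
write_rtstruct_file <- function(path, contours) {
  rois <- unique(vapply(contours, function(ct) ct$roi, character(1)))
  ss_items <- lapply(seq_along(rois), function(i) c(
    dcm_element(0x3006, 0x0022, "IS", as.character(i)),
    dcm_element(0x3006, 0x0026, "LO", rois[i])))
  rc_items <- lapply(seq_along(rois), function(i) {
    cts <- Filter(function(ct) ct$roi == rois[i], contours)
    ct_items <- lapply(cts, function(ct) {
      pts <- cbind(ct$vertices, ct$z)
      c(dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS",
                    paste(sprintf("%.6g", as.vector(t(pts))), collapse = "\\")))
    })
    c(as.raw(dcm_sequence(0x3006, 0x0040, ct_items)),
      dcm_element(0x3006, 0x0084, "IS", as.character(i)))
  })
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    dcm_element(0x0008, 0x0018, "UI", "1.2.826.0.1.99999.2.1"),
    dcm_sequence(0x3006, 0x0020, ss_items),
    dcm_sequence(0x3006, 0x0039, rc_items))
  writeBin(c(dcm_preamble_meta("1.2.840.10008.5.1.4.1.1.481.3",
                               "1.2.826.0.1.99999.2.1"), body), path)
  invisible(path)
}
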