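# Minimal single-frame CT DICOM support: uncompressed little-endian
# transfer syntaxes only (implicit 1.2.840.10008.1.2 and explicit
# 1.2.840.10008.1.2.1), which covers classic CT Image Storage as exported
# by scanners and by this package's own writer.

.UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"
.UID_ROOT        <- "1.2.826.0.1.3680043.10.1462"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# implicit-VR dictionary for the tags this package interprets
.DICT <- c(
  "00020010" = "UI", "00080016" = "UI", "00080018" = "UI", "00080060" = "CS",
  "00189345" = "FD", "00200013" = "IS", "00200032" = "DS", "00280002" = "US",
  "00280004" = "CS", "00280010" = "US", "00280011" = "US", "00280030" = "DS",
  "00280100" = "US", "00280101" = "US", "00280102" = "US", "00280103" = "US",
  "00281052" = "DS", "00281053" = "DS", "7FE00010" = "OW")

.u16 <- function(raw, pos)
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
.u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

.tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

.parse_elements <- function(raw, pos, explicit, stop_before_group = NULL) {
  elements <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- .u16(raw, pos)
    if (!is.null(stop_before_group) && group != stop_before_group) break
    elem <- .u16(raw, pos + 2L)
    key <- .tag_key(group, elem)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- if (key %in% names(.DICT)) .DICT[[key]] else "UN"
      len <- .u32(raw, pos + 4L); hdr <- 8L
    }
    pos <- pos + hdr
    if (len == 2^32 - 1) {
      # undefined length (sequences): scan for the sequence delimitation
      # item (FFFE,E0DD); sufficient for the non-pixel sequences CT files
      # carry, which this package ignores.
      delim <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
      found <- FALSE
      for (p in seq(pos, n - 7L)) {
        if (identical(raw[p:(p + 3L)], delim)) {
          pos <- p + 8L; found <- TRUE; break
        }
      }
      if (!found) stop("unterminated undefined-length element at tag ", key)
      next
    }
    if (pos + len - 1L > n)
      stop("truncated DICOM element at tag ", key)
    bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    elements[[key]] <- list(vr = vr, bytes = bytes)
    pos <- pos + len
  }
  list(elements = elements, pos = pos)
}

.el_str <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$bytes[el$bytes != as.raw(0)])
  trimws(s)
}
.el_ds <- function(el) {
  s <- .el_str(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.el_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
}
.el_fd <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "double", size = 8L, endian = "little")
}

#' Read a single-frame DICOM file
#'
#' Parses a classic single-frame DICOM file stored in the implicit or
#' explicit little-endian transfer syntax and decodes the attributes needed
#' for dosimetry: pixel data, rescale slope/intercept, pixel spacing, image
#' position, instance number, and CTDIvol (0018,9345).
#'
#' @param path Path to a DICOM file.
#' @return An object of class `dicom_file`: a list with `stored` (integer
#'   matrix of stored pixel values, row 1 = image top), `slope`,
#'   `intercept`, `pixel_spacing_mm`, `z_position_mm`, `instance_number`,
#'   `ctdi_vol_mGy` (or `NULL`), `sop_instance_uid`, `path`, and the raw
#'   `elements` table.
#' @seealso [load_series()] to read a whole series, [dicom_write()] for the
#'   matching writer.
#' @export
dicom_read <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a DICOM file (too short): ", path)
  pos <- 1L
  ts <- .UID_IMPLICIT_LE
  if (length(raw) >= 132L &&
      identical(rawToChar(raw[129:132]), "DICM")) {
    meta <- .parse_elements(raw, 133L, explicit = TRUE,
                            stop_before_group = 0x0002L)
    pos <- meta$pos
    ts_el <- meta$elements[["00020010"]]
    if (!is.null(ts_el)) ts <- .el_str(ts_el)
  } else {
    # no preamble: sniff explicit VR from the first element
    vr_guess <- rawToChar(raw[5:6])
    ts <- if (grepl("^[A-Z]{2}$", vr_guess)) .UID_EXPLICIT_LE
          else .UID_IMPLICIT_LE
  }
  if (!ts %in% c(.UID_IMPLICIT_LE, .UID_EXPLICIT_LE))
    stop("unsupported transfer syntax ", ts, " in ", path)
  parsed <- .parse_elements(raw, pos, explicit = ts == .UID_EXPLICIT_LE)
  el <- parsed$elements
  px <- el[["7FE00010"]]
  if (is.null(px)) stop("no PixelData in ", path)
  rows <- .el_us(el[["00280010"]])
  cols <- .el_us(el[["00280011"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  bits <- .el_us(el[["00280100"]]); if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit pixel data supported (got ", bits, ")")
  signed <- identical(.el_us(el[["00280103"]]), 1L)
  vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  stored <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  slope <- .el_ds(el[["00281053"]]); if (is.null(slope)) slope <- 1
  intercept <- .el_ds(el[["00281052"]]); if (is.null(intercept)) intercept <- 0
  ipp <- .el_ds(el[["00200032"]])
  inst <- .el_str(el[["00200013"]])
  structure(list(
    stored = stored, slope = slope[1], intercept = intercept[1],
    pixel_spacing_mm = .el_ds(el[["00280030"]]),
    z_position_mm = if (length(ipp) >= 3) ipp[3] else NULL,
    instance_number = if (is.null(inst)) NULL else as.integer(inst),
    ctdi_vol_mGy = .el_fd(el[["00189345"]]),
    sop_instance_uid = .el_str(el[["00080018"]]),
    path = path, elements = el), class = "dicom_file")
}

#' Extract CTDIvol from DICOM metadata
#'
#' Returns the CTDIvol (tag 0018,9345) recorded in a DICOM file, or an
#' explicit user override when supplied.  The override always wins over the
#' tag, so a known console value can replace a missing or wrong header.
#'
#' @param x A `dicom_file` (from [dicom_read()]) or a `ct_slice`.
#' @param override Optional CTDIvol in mGy that takes precedence over the
#'   tag.
#' @return CTDIvol in mGy, or `NULL` when neither tag nor override is
#'   available.  A negative tag value is treated as absent with a warning.
#' @export
read_ctdi_vol <- function(x, override = NULL) {
  if (!is.null(override)) {
    override <- as.numeric(override)
    if (override <= 0) stop("CTDIvol override must be positive")
    return(override)
  }
  v <- x$ctdi_vol_mGy
  if (is.null(v)) return(NULL)
  if (v < 0) {
    warning("negative CTDIvol tag value (", v, " mGy) treated as absent")
    return(NULL)
  }
  v
}

#' Convert a parsed DICOM file to a CT slice
#'
#' @param d A `dicom_file` from [dicom_read()].
#' @param slice_index Ordinal assigned within the series.
#' @param ctdi_vol_override Optional CTDIvol (mGy) overriding the tag.
#' @return A [ct_slice()] with HU values from the rescale
#'   `slope * stored + intercept`, clipped below at -1024.
#' @export
dicom_to_slice <- function(d, slice_index = 1L, ctdi_vol_override = NULL) {
  sp <- d$pixel_spacing_mm
  if (is.null(sp) || length(sp) != 2L || any(sp <= 0))
    stop("PixelSpacing missing or invalid in ", d$path,
         " (physical pixel area is required for Dw)")
  ct_slice(to_hu(d$stored, d$slope, d$intercept), sp,
           ctdi_vol_mGy = read_ctdi_vol(d, ctdi_vol_override),
           slice_index = slice_index, source_id = d$path,
           z_position_mm = d$z_position_mm)
}

#' Load an axial CT series
#'
#' Reads every DICOM file in a directory (or an explicit file list) and
#' returns the slices ordered by axial position: ImagePositionPatient z
#' when available on all slices, otherwise InstanceNumber, otherwise file
#' order.
#'
#' @param path A directory containing DICOM files, or a character vector of
#'   file paths.
#' @param ctdi_vol_override Optional CTDIvol (mGy) applied to every slice,
#'   overriding any tag values.
#' @return A list of [ct_slice()] objects with `slice_index` 1..n in
#'   spatial order.
#' @export
load_series <- function(path, ctdi_vol_override = NULL) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, full.names = TRUE) else path
  files <- files[file.exists(files) & !dir.exists(files)]
  dcms <- list()
  for (f in sort(files)) {
    d <- tryCatch(dicom_read(f), error = function(e) NULL)
    if (!is.null(d)) dcms[[length(dcms) + 1L]] <- d
  }
  if (length(dcms) == 0L) stop("empty series: no readable DICOM under ", path[1])
  dims <- vapply(dcms, function(d) dim(d$stored), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent matrix sizes across series")
  zs <- vapply(dcms, function(d)
    if (is.null(d$z_position_mm)) NA_real_ else d$z_position_mm, 0)
  ins <- vapply(dcms, function(d)
    if (is.null(d$instance_number)) NA_real_ else as.numeric(d$instance_number), 0)
  ord <- if (!anyNA(zs)) order(zs)
         else if (!anyNA(ins)) order(ins)
         else seq_along(dcms)
  dcms <- dcms[ord]
  lapply(seq_along(dcms), function(i)
    dicom_to_slice(dcms[[i]], slice_index = i,
                   ctdi_vol_override = ctdi_vol_override))
}

## ---- writer -----------------------------------------------------------

.w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")
.w_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                               endian = "little")

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.encode_element <- function(group, elem, vr, bytes) {
  bytes <- .pad_even(bytes, pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  hdr <- c(.w_u16(group), .w_u16(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS)
    c(hdr, as.raw(c(0, 0)), .w_u32(length(bytes)), bytes)
  else
    c(hdr, .w_u16(length(bytes)), bytes)
}

.enc_str <- function(group, elem, vr, s)
  .encode_element(group, elem, vr, charToRaw(as.character(s)))
.enc_us <- function(group, elem, x)
  .encode_element(group, elem, "US", .w_u16(x))
.enc_fd <- function(group, elem, x)
  .encode_element(group, elem, "FD",
                  writeBin(as.double(x), raw(), size = 8L, endian = "little"))

#' Write a CT slice as a single-frame DICOM file
#'
#' Serializes a [ct_slice()] to explicit-VR little-endian DICOM (CT Image
#' Storage).  Stored values are `round((HU - intercept) / slope)` as signed
#' 16-bit integers, so a round trip through [dicom_read()] reproduces the
#' HU grid to within rescale quantization (at most `slope/2` HU).
#'
#' @param slice A [ct_slice()].
#' @param path Output file path.
#' @param slope,intercept Rescale coefficients to encode with (defaults 1
#'   and -1024, the common CT convention).
#' @return `path`, invisibly.
#' @export
dicom_write <- function(slice, path, slope = 1, intercept = -1024) {
  stopifnot(inherits(slice, "ct_slice"))
  stored <- round((slice$hu - intercept) / slope)
  if (any(stored < -32768 | stored > 32767))
    stop("stored values exceed 16-bit signed range; adjust slope/intercept")
  nr <- nrow(slice$hu); nc <- ncol(slice$hu)
  # row-major pixel order
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  uid <- paste0(.UID_ROOT, ".", slice$slice_index, ".",
                sum(abs(stored)) %% 99991L)
  z <- if (is.null(slice$z_position_mm)) slice$slice_index * 1.0
       else slice$z_position_mm

  meta_body <- c(
    .encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .enc_str(0x0002, 0x0002, "UI", .UID_CT_STORAGE),
    .enc_str(0x0002, 0x0003, "UI", uid),
    .enc_str(0x0002, 0x0010, "UI", .UID_EXPLICIT_LE),
    .enc_str(0x0002, 0x0012, "UI", .UID_ROOT))
  meta <- c(.encode_element(0x0002, 0x0000, "UL", .w_u32(length(meta_body))),
            meta_body)

  body <- c(
    .enc_str(0x0008, 0x0016, "UI", .UID_CT_STORAGE),
    .enc_str(0x0008, 0x0018, "UI", uid),
    .enc_str(0x0008, 0x0060, "CS", "CT"),
    if (!is.null(slice$ctdi_vol_mGy))
      .enc_fd(0x0018, 0x9345, slice$ctdi_vol_mGy),
    .enc_str(0x0020, 0x0013, "IS", as.character(slice$slice_index)),
    .enc_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%.6g", z)),
    .enc_us(0x0028, 0x0002, 1L),
    .enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .enc_us(0x0028, 0x0010, nr),
    .enc_us(0x0028, 0x0011, nc),
    .enc_str(0x0028, 0x0030, "DS",
             sprintf("%.8g\\%.8g", slice$pixel_spacing_mm[1],
                     slice$pixel_spacing_mm[2])),
    .enc_us(0x0028, 0x0100, 16L),
    .enc_us(0x0028, 0x0101, 16L),
    .enc_us(0x0028, 0x0102, 15L),
    .enc_us(0x0028, 0x0103, 1L),
    .enc_str(0x0028, 0x1052, "DS", sprintf("%.8g", intercept)),
    .enc_str(0x0028, 0x1053, "DS", sprintf("%.8g", slope)),
    .encode_element(0x7FE0, 0x0010, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
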