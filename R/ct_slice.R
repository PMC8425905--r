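#' Construct a CT slice
#'
#' Container for one axial CT image: a matrix of Hounsfield Units (row 1 is
#' the top of the image), physical pixel spacing, and optional per-slice
#' CTDIvol.
#'
#' @param hu Numeric matrix of Hounsfield Units.  Values below -1024 are
#'   clipped to -1024 (scanner padding guard).
#' @param pixel_spacing_mm Length-2 numeric, (row, column) pixel spacing in
#'   millimetres; both must be positive.
#' @param ctdi_vol_mGy Optional non-negative CTDIvol in mGy for this slice;
#'   `NULL` when unknown.
#' @param slice_index Ordinal of the slice within its series.
#' @param source_id Free-text provenance (file path or `"synthetic"`).
#' @param z_position_mm Optional axial position (ImagePositionPatient z),
#'   used to order a series.
#'
#' @return An object of class `ct_slice`: a list with elements `hu`,
#'   `pixel_spacing_mm`, `ctdi_vol_mGy`, `slice_index`, `source_id`,
#'   `z_position_mm`.
#' @export
#' @examples
#' sl <- ct_slice(matrix(0, 32, 32), c(0.8, 0.8))
#' dim(sl$hu)
ct_slice <- function(hu, pixel_spacing_mm, ctdi_vol_mGy = NULL,
                     slice_index = 1L, source_id = "synthetic",
                     z_position_mm = NULL) {
  if (!is.matrix(hu) || !is.numeric(hu))
    stop("'hu' must be a numeric matrix")
  if (nrow(hu) < 16L || ncol(hu) < 16L)
    stop("HU grid must be at least 16 x 16")
  if (any(!is.finite(hu)))
    stop("HU grid contains non-finite values")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("'pixel_spacing_mm' must be two positive numbers (row, col)")
  hu[hu < -1024] <- -1024
  if (!is.null(ctdi_vol_mGy)) {
    ctdi_vol_mGy <- as.numeric(ctdi_vol_mGy)
    if (length(ctdi_vol_mGy) != 1L || is.na(ctdi_vol_mGy) || ctdi_vol_mGy < 0)
      stop("'ctdi_vol_mGy' must be a single non-negative number or NULL")
  }
  structure(
    list(hu = hu, pixel_spacing_mm = pixel_spacing_mm,
         ctdi_vol_mGy = ctdi_vol_mGy, slice_index = as.integer(slice_index),
         source_id = source_id, z_position_mm = z_position_mm),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.4g x %.4g mm, HU [%g, %g]\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing_mm[1],
              x$pixel_spacing_mm[2], min(x$hu), max(x$hu)))
  cat(sprintf("  slice_index %d, CTDIvol %s, source %s\n", x$slice_index,
              if (is.null(x$ctdi_vol_mGy)) "absent"
              else sprintf("%.3g mGy", x$ctdi_vol_mGy), x$source_id))
  invisible(x)
}

#' Convert stored pixel values to Hounsfield Units
#'
#' Applies the DICOM linear rescale `HU = slope * stored + intercept` and
#' clips the result below at -1024 HU so that scanner padding values outside
#' the reconstruction circle cannot fall below air.
#'
#' @param stored_values Integer or numeric matrix of stored pixel values.
#' @param slope Rescale slope; must be non-zero.
#' @param intercept Rescale intercept.
#' @return Numeric matrix of HU, same shape as `stored_values`.
#' @export
#' @examples
#' to_hu(matrix(1024, 1, 1), 1, -1024)  # water -> 0 HU
to_hu <- function(stored_values, slope, intercept) {
  slope <- as.numeric(slope)
  if (length(slope) != 1L || !is.finite(slope) || slope == 0)
    stop("rescale slope must be a single non-zero number")
  hu <- slope * stored_values + as.numeric(intercept)
  hu[hu < -1024] <- -1024
  hu
}
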