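# Dw, f_size, SSDE and old-vs-new percentage differences.

#' Water-equivalent diameter of a masked region
#'
#' Computes the diameter of the water cylinder with the same total x-ray
#' attenuation as the masked region:
#' \deqn{D_w = 2\sqrt{\left(\frac{\overline{HU}}{1000}+1\right)\frac{A_{ROI}}{\pi}}}
#' with the mean HU taken over the mask and the physical area
#' `A_ROI = n_pixels * row_spacing * col_spacing / 100` in cm^2.
#'
#' @param hu Numeric HU matrix, or a [ct_slice()] (pixel spacing is then
#'   taken from the slice).
#' @param mask A `body_mask` from the contouring functions, or a logical
#'   matrix of the same shape as `hu`.  Must be non-empty.
#' @param pixel_spacing_mm Length-2 (row, col) spacing in mm; ignored when
#'   `hu` is a `ct_slice`.
#' @param slice_index Ordinal stored in the result.
#' @return A `dw_result`: list with `slice_index`, `area_cm2`, `mean_hu`,
#'   `dw_cm`.
#' @export
#' @examples
#' hu <- matrix(-1000, 64, 64)
#' hu[20:44, 20:44] <- 0                       # 25 x 25 px water block
#' m <- hu >= -200
#' water_equivalent_diameter(hu, m, c(0.8, 0.8))$dw_cm
water_equivalent_diameter <- function(hu, mask, pixel_spacing_mm = NULL,
                                      slice_index = 1L) {
  if (inherits(hu, "ct_slice")) {
    pixel_spacing_mm <- hu$pixel_spacing_mm
    slice_index <- hu$slice_index
    hu <- hu$hu
  }
  if (inherits(mask, "body_mask")) mask <- mask$mask
  if (!identical(dim(hu), dim(mask)))
    stop("mask and HU grid dimensions differ")
  if (is.null(pixel_spacing_mm))
    stop("pixel spacing required to compute area in cm^2")
  n <- sum(mask)
  if (n == 0L) stop("empty mask: no ROI to measure")
  vals <- hu[mask]
  mean_hu <- mean(vals)
  a_px <- pixel_spacing_mm[1] * pixel_spacing_mm[2] / 100
  area_cm2 <- n * a_px
  # accumulate the water-equivalent pixel count term by term: air pixels
  # (HU -1000) contribute exactly 0, so enlarging the ROI by air leaves
  # Dw bit-identical; algebraically this equals (meanHU/1000 + 1) * A_ROI
  radicand <- sum(vals / 1000 + 1) * a_px
  if (radicand < 0)
    stop("negative water-equivalent area (mean HU below -1000)")
  structure(list(slice_index = as.integer(slice_index), area_cm2 = area_cm2,
                 mean_hu = mean_hu, dw_cm = 2 * sqrt(radicand / pi)),
            class = "dw_result")
}

#' @export
print.dw_result <- function(x, ...) {
  cat(sprintf("<dw_result> slice %d: A_ROI %.2f cm^2, mean HU %.1f, Dw %.2f cm\n",
              x$slice_index, x$area_cm2, x$mean_hu, x$dw_cm))
  invisible(x)
}

#' Series-mean water-equivalent diameter
#'
#' @param results Non-empty list of `dw_result` objects.
#' @return Unweighted arithmetic mean of `dw_cm` across slices.
#' @export
mean_dw <- function(results) {
  if (length(results) == 0L) stop("no Dw results to average")
  mean(vapply(results, `[[`, 0, "dw_cm"))
}

.fsize_table <- function() {
  path <- system.file("extdata", "fsize_coefficients.csv", package = "ctdose",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Size conversion factor from water-equivalent diameter
#'
#' Evaluates the AAPM Report 204 exponential fit
#' `f_size = a * exp(-b * Dw)` for the chosen reference phantom.  The
#' coefficients ship as an editable table
#' (`system.file("extdata", "fsize_coefficients.csv", package = "ctdose")`)
#' so alternative fits can be dropped in.
#'
#' @param dw_cm Water-equivalent diameter in cm; must be positive.  Values
#'   outside the supported 6-55 cm range are extrapolated with a warning.
#' @param phantom_ref `"body-32cm"` (default) or `"head-16cm"`, the PMMA
#'   phantom CTDIvol is referenced to.
#' @param coefficients Optional data frame with columns `phantom_ref`, `a`,
#'   `b` replacing the shipped table.
#' @return The dimensionless conversion factor.
#' @export
#' @examples
#' size_conversion_factor(25)                 # adult body, f > 1
#' size_conversion_factor(16, "head-16cm")
size_conversion_factor <- function(dw_cm,
                                   phantom_ref = c("body-32cm", "head-16cm"),
                                   coefficients = NULL) {
  phantom_ref <- match.arg(phantom_ref)
  if (any(dw_cm <= 0)) stop("Dw must be positive")
  if (any(dw_cm < 6 | dw_cm > 55))
    warning("Dw outside the 6-55 cm supported range; extrapolating the fit")
  tab <- if (is.null(coefficients)) .fsize_table() else coefficients
  row <- tab[tab$phantom_ref == phantom_ref, , drop = FALSE]
  if (nrow(row) != 1L) stop("no coefficients for phantom ", phantom_ref)
  row$a * exp(-row$b * dw_cm)
}

#' Size-specific dose estimate
#'
#' `SSDE = CTDIvol * f_size` (mGy).
#'
#' @param ctdi_vol_mGy CTDIvol in mGy; must be positive.
#' @param f_size Size conversion factor from [size_conversion_factor()].
#' @return SSDE in mGy.
#' @export
ssde <- function(ctdi_vol_mGy, f_size) {
  if (any(ctdi_vol_mGy <= 0)) stop("CTDIvol must be positive")
  if (any(f_size <= 0)) stop("f_size must be positive")
  ctdi_vol_mGy * f_size
}

#' Percentage difference between new- and old-algorithm Dw
#'
#' `100 * (Dw_new - Dw_old) / Dw_old`: positive when the improved contour
#' captures more of the patient.
#'
#' @param dw_new,dw_old Dw values (cm); `dw_old` must be positive.
#' @return Percentage difference.
#' @export
percent_diff_dw <- function(dw_new, dw_old) {
  if (any(dw_old <= 0)) stop("reference Dw must be positive")
  (dw_new - dw_old) / dw_old * 100
}

#' Percentage difference between new- and old-algorithm SSDE
#'
#' `100 * (SSDE_new - SSDE_old) / SSDE_old`: negative when the larger new
#' Dw lowers the conversion factor.
#'
#' @param ssde_new,ssde_old SSDE values (mGy); `ssde_old` must be positive.
#' @return Percentage difference.
#' @export
percent_diff_ssde <- function(ssde_new, ssde_old) {
  if (any(ssde_old <= 0)) stop("reference SSDE must be positive")
  (ssde_new - ssde_old) / ssde_old * 100
}
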