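# Synthetic elliptical phantoms with closed-form ground truth.  Scenes are
# described in physical cm (y measured from the image top, x from the
# left); rendering places each pixel by its centre, so the discrete mask
# is unambiguous and the analytic oracle error is pure rasterization.

#' Describe one elliptical body part
#'
#' @param center_cm Length-2 (y, x) centre in cm from the image top-left.
#' @param semi_axes_cm Length-2 (y, x) semi-axes in cm.
#' @param hu Tissue HU; must be >= -200 so thresholding detects the body.
#' @param cavities Optional list of nested ellipses (same fields, any HU,
#'   e.g. lung at -800) fully contained in the body ellipse.
#' @return A `phantom_body` list.
#' @export
phantom_body <- function(center_cm, semi_axes_cm, hu = 40, cavities = list()) {
  if (hu < -200)
    stop("body HU must be >= -200 so the threshold detects it")
  for (cav in cavities) {
    ok <- all(abs(cav$center_cm - center_cm) + cav$semi_axes_cm <= semi_axes_cm)
    if (!ok) stop("cavity not contained in its body ellipse")
  }
  structure(list(center_cm = center_cm, semi_axes_cm = semi_axes_cm,
                 hu = hu, cavities = cavities), class = "phantom_body")
}

#' Describe a CT-table object
#'
#' Either a thin horizontal strip (`shape = "strip"`, a rectangle of
#' half-extents `half_extent_cm`) or a shallow arc (`shape = "arc"`, the
#' lower part of an annulus of the given radius and thickness centred
#' above the table).
#'
#' @param center_cm (y, x) centre in cm.  For the arc, the centre of the
#'   supporting circle.
#' @param half_extent_cm (y, x) half-extents in cm (strip only).
#' @param hu Table HU (default 200, a dense support).
#' @param shape `"strip"` or `"arc"`.
#' @param radius_cm,thickness_cm Arc geometry (arc only).
#' @param true_table Declares that this object is meant to be removed by
#'   the table rule; its centroid must then fall below the table line.
#' @return A `phantom_table` list.
#' @export
phantom_table <- function(center_cm, half_extent_cm = c(0.5, 12), hu = 200,
                          shape = c("strip", "arc"), radius_cm = 18,
                          thickness_cm = 1, true_table = TRUE) {
  shape <- match.arg(shape)
  structure(list(center_cm = center_cm, half_extent_cm = half_extent_cm,
                 hu = hu, shape = shape, radius_cm = radius_cm,
                 thickness_cm = thickness_cm, true_table = true_table),
            class = "phantom_table")
}

#' Assemble a phantom scene description
#'
#' @param bodies List of [phantom_body()] objects (1-3 in the emulated
#'   scenes).
#' @param table Optional [phantom_table()].
#' @param n_rows,n_cols Matrix size (default 512 x 512).
#' @param pixel_spacing_mm (row, col) spacing in mm (default 0.8 x 0.8).
#' @param background_hu Background air HU (default -1000).
#' @param ctdi_vol_mGy Optional CTDIvol attached to rendered slices.
#' @param seed Integer recorded with the spec (jitter provenance).
#' @return A `phantom_spec` list; every body ellipse is checked to lie
#'   fully inside the grid.
#' @export
#' @examples
#' spec <- phantom_spec(list(phantom_body(c(20, 20), c(10, 10), hu = 0)))
#' analytic_dw(spec)  # 20 cm water disc -> 20
phantom_spec <- function(bodies, table = NULL, n_rows = 512L, n_cols = 512L,
                         pixel_spacing_mm = c(0.8, 0.8),
                         background_hu = -1000, ctdi_vol_mGy = NULL,
                         seed = NULL) {
  ext <- c(n_rows * pixel_spacing_mm[1], n_cols * pixel_spacing_mm[2]) / 10
  for (b in bodies) {
    if (!inherits(b, "phantom_body")) stop("bodies must be phantom_body objects")
    if (any(b$center_cm - b$semi_axes_cm < 0) ||
        any(b$center_cm + b$semi_axes_cm > ext))
      stop("body ellipse extends outside the image grid")
  }
  if (!is.null(table) && isTRUE(table$true_table)) {
    limit_cm <- round(400 * n_rows / 512) * pixel_spacing_mm[1] / 10
    # material centroid: strip centre, or the centroid of a thin
    # semicircular band (2R/pi below the supporting-circle centre)
    centroid_y <- if (table$shape == "strip") table$center_cm[1]
      else table$center_cm[1] +
        (2 / pi) * (table$radius_cm + table$thickness_cm / 2)
    if (centroid_y <= limit_cm)
      stop("true table centroid must lie below the table line (",
           signif(limit_cm, 4), " cm)")
  }
  structure(list(bodies = bodies, table = table, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 pixel_spacing_mm = pixel_spacing_mm,
                 background_hu = background_hu, ctdi_vol_mGy = ctdi_vol_mGy,
                 seed = seed), class = "phantom_spec")
}

.ellipse_px <- function(n_rows, n_cols, sp_mm, center_cm, semi_cm) {
  y <- (seq_len(n_rows) - 0.5) * sp_mm[1] / 10
  x <- (seq_len(n_cols) - 0.5) * sp_mm[2] / 10
  outer(((y - center_cm[1]) / semi_cm[1])^2,
        ((x - center_cm[2]) / semi_cm[2])^2, `+`) <= 1
}

.table_px <- function(tab, n_rows, n_cols, sp_mm) {
  y <- (seq_len(n_rows) - 0.5) * sp_mm[1] / 10
  x <- (seq_len(n_cols) - 0.5) * sp_mm[2] / 10
  if (tab$shape == "strip") {
    outer(abs(y - tab$center_cm[1]) <= tab$half_extent_cm[1],
          abs(x - tab$center_cm[2]) <= tab$half_extent_cm[2], `&`)
  } else {
    r <- sqrt(outer((y - tab$center_cm[1])^2, (x - tab$center_cm[2])^2, `+`))
    below <- matrix(y > tab$center_cm[1], n_rows, n_cols)
    r >= tab$radius_cm & r <= tab$radius_cm + tab$thickness_cm & below
  }
}

#' Rasterize a phantom scene
#'
#' Renders the scene onto the HU grid by pixel-centre point-in-ellipse
#' tests (no anti-aliasing) and returns the slice together with the
#' ground-truth patient mask: the union of the filled body ellipses, with
#' cavities (lungs) included, exactly as the contouring pipeline should
#' recover them.
#'
#' @param spec A [phantom_spec()].
#' @return List with `slice` (a [ct_slice()]) and `truth_mask` (logical
#'   matrix).  Rendering is deterministic for a fixed spec; a table
#'   overlapping a body is an error (scenes keep them disjoint).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  hu <- matrix(spec$background_hu, spec$n_rows, spec$n_cols)
  truth <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (b in spec$bodies) {
    m <- .ellipse_px(spec$n_rows, spec$n_cols, spec$pixel_spacing_mm,
                     b$center_cm, b$semi_axes_cm)
    hu[m] <- b$hu
    truth <- truth | m
    for (cav in b$cavities) {
      cm <- .ellipse_px(spec$n_rows, spec$n_cols, spec$pixel_spacing_mm,
                        cav$center_cm, cav$semi_axes_cm)
      hu[cm] <- cav$hu
    }
  }
  if (!is.null(spec$table)) {
    tm <- .table_px(spec$table, spec$n_rows, spec$n_cols,
                    spec$pixel_spacing_mm)
    if (any(tm & truth)) stop("table overlaps a body part")
    hu[tm] <- spec$table$hu
  }
  list(slice = ct_slice(hu, spec$pixel_spacing_mm,
                        ctdi_vol_mGy = spec$ctdi_vol_mGy,
                        source_id = "synthetic"),
       truth_mask = truth)
}

#' Closed-form water-equivalent diameter of a phantom
#'
#' Analytic oracle computed from the continuous geometry, with no
#' rasterization: the patient area is the sum of the filled ellipse areas
#' `pi * a * b` (cavities count toward the area, as lungs do inside the
#' chest contour), the mean HU is the area-weighted mean of the
#' constituent tissue HUs (cavities at their own HU), and Dw follows the
#' same formula as [water_equivalent_diameter()].
#'
#' @param spec A [phantom_spec()].
#' @return Dw in cm, with attributes `area_cm2` and `mean_hu`.
#' @export
analytic_dw <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  area <- 0; husum <- 0
  for (b in spec$bodies) {
    a_body <- pi * b$semi_axes_cm[1] * b$semi_axes_cm[2]
    a_cav <- vapply(b$cavities, function(cv)
      pi * cv$semi_axes_cm[1] * cv$semi_axes_cm[2], 0)
    hu_cav <- vapply(b$cavities, `[[`, 0, "hu")
    area <- area + a_body
    husum <- husum + (a_body - sum(a_cav)) * b$hu + sum(a_cav * hu_cav)
  }
  mean_hu <- husum / area
  dw <- 2 * sqrt((mean_hu / 1000 + 1) * area / pi)
  attr(dw, "area_cm2") <- area
  attr(dw, "mean_hu") <- mean_hu
  dw
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Parameterized scene library
#'
#' Builds a [phantom_spec()] emulating one of five axial scene classes:
#' `"pelvis"` (one soft-tissue ellipse), `"chest_arms_up"` (torso with two
#' lung cavities), `"chest_one_arm_down"` / `"chest_two_arms_down"` (torso
#' plus one / two separated arm ellipses), and `"two_legs"` (two disjoint
#' ellipses of comparable area).  Every scene includes a table strip whose
#' centroid lies below the 400-pixel table line.  Soft tissue is 40 HU,
#' lung -800 HU, table 200 HU, background -1000 HU; CTDIvol is 10 mGy.
#'
#' @param name Scene class name.
#' @param size_scale Global anatomical scale in \[0.5, 1.5\]; semi-axes and
#'   lateral offsets scale together so parts stay separated and inside the
#'   grid.
#' @param seed Optional integer adding reproducible jitter (about +/-3% on
#'   the scale and +/-3 mm vertically); `NULL` gives the nominal geometry.
#' @return A `phantom_spec`.
#' @export
#' @examples
#' spec <- scene_library("chest_two_arms_down", size_scale = 1, seed = 7)
#' length(spec$bodies)  # torso + two arms
scene_library <- function(name = c("pelvis", "chest_arms_up",
                                   "chest_one_arm_down",
                                   "chest_two_arms_down", "two_legs"),
                          size_scale = 1, seed = NULL) {
  name <- match.arg(name)
  if (size_scale < 0.5 || size_scale > 1.5)
    stop("size_scale must be in [0.5, 1.5]")
  jit <- .with_seed(seed, c(runif(1, 0.97, 1.03), runif(1, -0.3, 0.3)))
  s <- size_scale * jit[1]
  dy <- jit[2]
  cx <- 512 * 0.08 / 2  # 20.48 cm, image centre
  soft <- 40; lung <- -800

  chest_torso <- function() {
    phantom_body(c(17 + dy, cx), c(8.5, 8.8) * s, hu = soft, cavities = list(
      list(center_cm = c(16.5 + dy, cx - 4.4 * s), semi_axes_cm = c(5.5, 3.8) * s,
           hu = lung),
      list(center_cm = c(16.5 + dy, cx + 4.4 * s), semi_axes_cm = c(5.5, 3.8) * s,
           hu = lung)))
  }
  arm <- function(side) {
    phantom_body(c(17 + dy + 1.0 * s, cx + side * 11.1 * s),
                 c(3.2, 1.8) * s, hu = soft)
  }
  bodies <- switch(name,
    pelvis = list(phantom_body(c(20.5 + dy, cx), c(8.5, 12.5) * s, hu = soft)),
    chest_arms_up = list(chest_torso()),
    chest_one_arm_down = list(chest_torso(), arm(-1)),
    chest_two_arms_down = list(chest_torso(), arm(-1), arm(+1)),
    two_legs = list(
      phantom_body(c(21 + dy, cx - 6.2 * s), c(7, 5.2) * s, hu = soft),
      phantom_body(c(21 + dy, cx + 6.2 * s), c(7, 5.2) * s, hu = soft)))
  phantom_spec(bodies,
               table = phantom_table(c(35.6, cx), c(0.5, 12), hu = 200),
               ctdi_vol_mGy = 10, seed = seed)
}
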