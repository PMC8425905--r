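# Body-contour segmentation: threshold at -200 HU, label connected
# components (8-connectivity), fill each component's outer contour, keep
# the k largest objects and drop those whose vertical centroid falls below
# the CT-table line.

#' Threshold an HU image
#'
#' Foreground is every pixel at or above the threshold (inclusive), so
#' tissue exactly at the threshold is kept.  The default -200 HU separates
#' soft tissue and bone from air and lung while leaving the patient
#' boundary intact.
#'
#' @param hu Numeric HU matrix.
#' @param threshold_hu Threshold in HU (default -200).
#' @return Logical matrix, `TRUE` for foreground.
#' @export
threshold_image <- function(hu, threshold_hu = -200) {
  if (!is.matrix(hu) || length(hu) == 0L) stop("'hu' must be a non-empty matrix")
  hu >= threshold_hu
}

# 8-connected labelling built on EBImage's 4-connected bwlabel: labels that
# touch diagonally are merged with a union-find pass over the label graph.
.label8 <- function(bin) {
  m <- matrix(as.numeric(bin), nrow = nrow(bin))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(bin))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- c(lab[-nr, -nc], lab[-nr, -1L])  # pixel vs its SE / SW neighbour
  b <- c(lab[-1L, -1L], lab[-1L, -nc])
  sel <- a > 0L & b > 0L & a != b
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (any(sel)) {
    pairs <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  new_id <- match(roots, sort(unique(roots)))
  matrix(c(0L, new_id)[lab + 1L], nrow = nr)
}

#' Label connected foreground objects and fill their contours
#'
#' Connected components are found under 8-connectivity (diagonal pixel
#' contacts do not split thin limbs).  Each component's outer contour is
#' then filled, so interior holes such as lung cavities become part of the
#' object; areas and centroids refer to the filled region.
#'
#' @param binary Logical (or 0/1) matrix from [threshold_image()].
#' @return A list of `component_info` objects, one per component, each with
#'   `label`, `area_px` (filled area), `centroid_rc` (row, col of the
#'   filled region, row 1 = image top), and `filled_mask` (logical matrix).
#'   An all-`FALSE` input yields an empty list.
#' @export
label_components <- function(binary) {
  if (!is.matrix(binary)) stop("'binary' must be a matrix")
  bin <- binary > 0
  if (!any(bin)) return(list())
  lab <- .label8(bin)
  lapply(seq_len(max(lab)), function(i) {
    solo <- lab == i
    filled <- EBImage::fillHull(matrix(as.numeric(solo),
                                       nrow = nrow(solo))) > 0
    idx <- which(filled, arr.ind = TRUE)
    structure(list(
      label = i,
      area_px = nrow(idx),
      centroid_rc = c(mean(idx[, 1]), mean(idx[, 2])),
      filled_mask = filled), class = "component_info")
  })
}

#' Select the k largest components
#'
#' @param components List of `component_info` from [label_components()].
#' @param k Number of objects to keep (default 6).  Fewer than `k`
#'   components: all are returned.  Area ties break by ascending label.
#' @return The `min(k, length(components))` largest components in
#'   descending filled-area order.
#' @export
select_largest <- function(components, k = 6L) {
  if (k < 1L) stop("'k' must be at least 1")
  if (length(components) == 0L) return(components)
  areas <- vapply(components, `[[`, 0, "area_px")
  labels <- vapply(components, `[[`, 0, "label")
  ord <- order(-areas, labels)
  components[ord[seq_len(min(k, length(components)))]]
}

#' Remove the CT table by vertical centroid position
#'
#' The patient couch sits near the image bottom; any object whose filled
#' centroid row lies more than `table_y_limit_px` pixels from the top (on a
#' 512-row matrix; scaled proportionally otherwise) is classified as table
#' and removed.
#'
#' @param components List of `component_info`.
#' @param table_y_limit_px Table line in pixels for a 512-row image
#'   (default 400).  The effective limit is
#'   `round(table_y_limit_px * n_rows / 512)`.
#' @param n_rows Number of image rows.
#' @return List with `retained` and `removed` component lists.  An empty
#'   `retained` set is an error: no patient was found above the table line.
#' @export
remove_table <- function(components, table_y_limit_px = 400L, n_rows) {
  limit <- round(table_y_limit_px * n_rows / 512)
  rows <- vapply(components, function(cc) cc$centroid_rc[1], 0)
  below <- rows > limit
  retained <- components[!below]
  if (length(retained) == 0L)
    stop("no patient found above table line (y limit ", limit, " px)")
  spans <- vapply(retained, function(cc) {
    rows_on <- which(rowSums(cc$filled_mask) > 0)
    if (length(rows_on)) max(rows_on) else 0
  }, 0)
  if (any(spans > limit))
    warning("a retained component extends below the table line ",
            "(table may touch the body); kept by centroid rule")
  list(retained = retained, removed = components[below])
}

.body_mask <- function(retained, removed, dims, params) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (cc in retained) mask <- mask | cc$filled_mask
  structure(list(mask = mask, retained = retained,
                 removed_as_table = removed, params = params),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %d x %d px, %d retained object(s), %d removed as table\n",
              nrow(x$mask), ncol(x$mask), length(x$retained),
              length(x$removed_as_table)))
  cat(sprintf("  area %d px; params: threshold %g HU, k %d, table line %d px\n",
              sum(x$mask), x$params$threshold_hu, x$params$k_objects,
              x$params$table_y_limit_px))
  invisible(x)
}

.contour_pipeline <- function(hu, threshold_hu, k_objects, table_y_limit_px) {
  bin <- threshold_image(hu, threshold_hu)
  comps <- label_components(bin)
  if (length(comps) == 0L)
    stop("no objects above ", threshold_hu, " HU in slice")
  top <- select_largest(comps, k_objects)
  remove_table(top, table_y_limit_px, n_rows = nrow(hu))
}

#' Body contour from the six largest objects (improved algorithm)
#'
#' Thresholds the slice, labels and fills connected objects, keeps the
#' `k_objects` largest, removes the CT table by centroid position, and
#' returns the union of the remaining filled objects as the patient mask.
#' Because every object is contour-filled, smaller objects nested inside
#' the largest one are absorbed into it, so single-body images reduce to
#' the legacy behaviour while separated arms or legs are retained.
#'
#' @param hu Numeric HU matrix (or a [ct_slice()]).
#' @param threshold_hu Segmentation threshold in HU (default -200).
#' @param k_objects Number of largest objects considered (default 6).
#' @param table_y_limit_px Table line for a 512-row image (default 400).
#' @return A `body_mask`: logical `mask`, the `retained` components, the
#'   components `removed_as_table`, and the `params` used.
#' @export
#' @examples
#' ph <- render_phantom(scene_library("two_legs", seed = 1))
#' bm <- contour_body_new(ph$slice)
#' length(bm$retained)  # both legs kept
contour_body_new <- function(hu, threshold_hu = -200, k_objects = 6L,
                             table_y_limit_px = 400L) {
  if (inherits(hu, "ct_slice")) hu <- hu$hu
  sel <- .contour_pipeline(hu, threshold_hu, k_objects, table_y_limit_px)
  .body_mask(sel$retained, sel$removed, dim(hu),
             list(threshold_hu = threshold_hu, k_objects = k_objects,
                  table_y_limit_px = table_y_limit_px, algorithm = "new"))
}

#' Body contour from the single largest object (legacy algorithm)
#'
#' Identical pipeline to [contour_body_new()] up to table removal, after
#' which only the single largest remaining object is kept as the patient
#' boundary.  On images with separated body parts (a lowered arm, two
#' legs) this underestimates the patient area.
#'
#' @inheritParams contour_body_new
#' @return A `body_mask` whose mask is the largest retained object only.
#' @export
contour_body_old <- function(hu, threshold_hu = -200, k_objects = 6L,
                             table_y_limit_px = 400L) {
  if (inherits(hu, "ct_slice")) hu <- hu$hu
  sel <- .contour_pipeline(hu, threshold_hu, k_objects, table_y_limit_px)
  largest <- select_largest(sel$retained, 1L)
  .body_mask(largest, sel$removed, dim(hu),
             list(threshold_hu = threshold_hu, k_objects = k_objects,
                  table_y_limit_px = table_y_limit_px, algorithm = "old"))
}
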