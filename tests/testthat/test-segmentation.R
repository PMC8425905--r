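test_that("thresholding is inclusive at the boundary", {
  hu <- matrix(c(0, -1000, -200, -200.001), 2, 2)
  expect_equal(threshold_image(hu), matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_error(threshold_image(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("labelling finds 8-connected components and fills contours", {
  g <- matrix(FALSE, 12, 12)
  g[2:4, 2:4] <- TRUE
  g[8:10, 8:10] <- TRUE
  comps <- label_components(g)
  expect_length(comps, 2)
  expect_equal(sort(vapply(comps, `[[`, 0, "area_px")), c(9, 9))

  # diagonal contact joins components (8-connectivity)
  d <- matrix(FALSE, 6, 6)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[4, 4] <- TRUE
  expect_length(label_components(d), 1)

  # a ring is one component whose filled mask includes the hole
  r <- matrix(FALSE, 9, 9)
  r[3:7, 3] <- TRUE; r[3:7, 7] <- TRUE; r[3, 3:7] <- TRUE; r[7, 3:7] <- TRUE
  comps <- label_components(r)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$area_px, 25)          # 5x5 filled square
  expect_true(comps[[1]]$filled_mask[5, 5])     # hole included
  expect_equal(comps[[1]]$centroid_rc, c(5, 5))

  expect_equal(label_components(matrix(FALSE, 4, 4)), list())
})

test_that("component area equals the true cells of its filled mask", {
  set.seed(42)
  for (i in 1:10) {
    g <- matrix(runif(400) > 0.7, 20, 20)
    for (cc in label_components(g)) {
      expect_equal(cc$area_px, sum(cc$filled_mask))
      expect_gte(cc$area_px, 1)
      expect_true(cc$centroid_rc[1] >= 1 && cc$centroid_rc[1] <= 20)
    }
  }
})

test_that("select_largest keeps the k biggest, ties by ascending label", {
  fake <- function(label, area)
    structure(list(label = label, area_px = area), class = "component_info")
  comps <- Map(fake, 1:8, c(900, 850, 10, 8, 7, 6, 5, 4))
  expect_equal(vapply(select_largest(comps, 6), `[[`, 0, "area_px"),
               c(900, 850, 10, 8, 7, 6))
  expect_length(select_largest(comps[1:2], 6), 2)
  tied <- list(fake(2, 50), fake(1, 50))
  expect_equal(select_largest(tied, 1)[[1]]$label, 1)
  expect_error(select_largest(comps, 0), "at least 1")
})

test_that("table removal splits on the scaled centroid-row limit", {
  fake <- function(row) structure(
    list(label = 1L, area_px = 10, centroid_rc = c(row, 50),
         filled_mask = matrix(FALSE, 512, 512)), class = "component_info")
  out <- remove_table(list(fake(450), fake(100)), 400, n_rows = 512)
  expect_length(out$retained, 1)
  expect_equal(out$retained[[1]]$centroid_rc[1], 100)
  expect_length(out$removed, 1)
  expect_error(remove_table(list(fake(480)), 400, n_rows = 512),
               "no patient found above table line")
  # limit scales with matrix size: 400 * 256 / 512 = 200
  fake256 <- function(row) structure(
    list(label = 1L, area_px = 10, centroid_rc = c(row, 50),
         filled_mask = matrix(FALSE, 256, 256)), class = "component_info")
  expect_length(remove_table(list(fake256(210), fake256(190)), 400,
                             n_rows = 256)$removed, 1)
})

test_that("improved contour keeps separated parts and drops the table", {
  ph <- render_phantom(scene_library("chest_two_arms_down", seed = 21))
  bm <- contour_body_new(ph$slice)
  expect_identical(bm$mask, ph$truth_mask)   # torso + both arms, no table
  expect_length(bm$retained, 3)
  expect_length(bm$removed_as_table, 1)
  expect_gt(bm$removed_as_table[[1]]$centroid_rc[1], 400)
})

test_that("only the six largest objects can contribute to the mask", {
  hu <- matrix(-1000, 512, 512)
  radii <- c(60, 40, 30, 25, 20, 15, 5)   # 7 disjoint discs, above the line
  cols <- c(70, 180, 260, 325, 380, 425, 455)
  for (i in seq_along(radii))
    hu <- paint_disc(hu, c(150, cols[i]), radii[i], 40)
  bm <- contour_body_new(hu)
  expect_length(bm$retained, 6)
  smallest <- paint_disc(matrix(-1000, 512, 512), c(150, cols[7]),
                         radii[7], 40) > -200
  expect_false(any(bm$mask & smallest))    # rank-7 object excluded
  # the smallest disc is retained once k admits it
  expect_length(contour_body_new(hu, k_objects = 7)$retained, 7)
})

test_that("legacy contour keeps only the largest object", {
  legs <- render_phantom(scene_library("two_legs", seed = 5))
  bo <- contour_body_old(legs$slice)
  expect_length(bo$retained, 1)
  expect_lt(sum(bo$mask), sum(legs$truth_mask))

  arm <- render_phantom(scene_library("chest_one_arm_down", seed = 5))
  bo <- contour_body_old(arm$slice)
  bn <- contour_body_new(arm$slice)
  expect_length(bo$retained, 1)            # torso only
  expect_equal(bo$retained[[1]]$area_px,
               max(vapply(bn$retained, `[[`, 0, "area_px")))
})

test_that("old and new contours agree exactly on single-component slices", {
  for (sc in c("pelvis", "chest_arms_up")) {
    ph <- render_phantom(scene_library(sc, seed = 9))
    expect_identical(contour_body_new(ph$slice)$mask,
                     contour_body_old(ph$slice)$mask)
  }
})

test_that("the improved mask is always a superset of the legacy mask", {
  for (sc in all_scenes) {
    ph <- render_phantom(scene_library(sc, size_scale = 0.9, seed = 13))
    bn <- contour_body_new(ph$slice)
    bo <- contour_body_old(ph$slice)
    expect_false(any(bo$mask & !bn$mask))
  }
})

test_that("a table below the line never changes the patient mask", {
  for (sc in c("pelvis", "two_legs")) {
    spec <- scene_library(sc, seed = 17)
    with_tab <- render_phantom(spec)
    spec$table <- NULL
    no_tab <- render_phantom(spec)
    expect_identical(contour_body_new(with_tab$slice)$mask,
                     contour_body_new(no_tab$slice)$mask)
    expect_identical(contour_body_old(with_tab$slice)$mask,
                     contour_body_old(no_tab$slice)$mask)
  }
})

test_that("mask equals the union of retained filled components", {
  ph <- render_phantom(scene_library("chest_one_arm_down", seed = 23))
  bm <- contour_body_new(ph$slice)
  u <- Reduce(`|`, lapply(bm$retained, `[[`, "filled_mask"))
  expect_identical(bm$mask, u)
  # lung cavities (enclosed by the torso contour) are inside the mask
  lungs <- ph$slice$hu < -200 & ph$truth_mask
  expect_true(any(lungs))
  expect_true(all(bm$mask[lungs]))
})
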