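test_that("Dw of a uniform water disc recovers its true diameter", {
  spec <- water_ellipse_spec(10, 10)           # 20 cm disc
  ph <- render_phantom(spec)
  bm <- contour_body_new(ph$slice)
  dw <- water_equivalent_diameter(ph$slice, bm)
  expect_equal(dw$dw_cm, 20, tolerance = 0.005)  # < 0.5 %
  expect_equal(dw$mean_hu, 0)
})

test_that("Dw hand-computed cases", {
  # mask of 400 cm^2 at mean HU +100 -> 2*sqrt(1.1*400/pi) = 23.6692 cm
  hu <- matrix(100, 256, 256)
  mask <- matrix(FALSE, 256, 256)
  mask[1:250, 1:250] <- TRUE                   # 62500 px * 0.64 mm^2 = 400 cm^2
  dw <- water_equivalent_diameter(hu, mask, c(0.8, 0.8))
  expect_equal(dw$area_cm2, 400)
  expect_equal(dw$dw_cm, 23.6692, tolerance = 1e-4)

  # uniform -1000 HU region has zero water-equivalent diameter
  dw0 <- water_equivalent_diameter(matrix(-1000, 64, 64),
                                   matrix(TRUE, 64, 64), c(0.8, 0.8))
  expect_equal(dw0$dw_cm, 0)

  expect_error(water_equivalent_diameter(hu, matrix(FALSE, 256, 256),
                                         c(0.8, 0.8)), "empty mask")
})

test_that("Dw satisfies its defining identity and the per-pixel oracle", {
  set.seed(7)
  for (i in 1:20) {
    hu <- matrix(runif(64 * 64, -1000, 500), 64, 64)
    mask <- matrix(runif(64 * 64) < 0.4, 64, 64)
    if (!any(mask)) next
    sp <- c(runif(1, 0.4, 1.2), runif(1, 0.4, 1.2))
    dw <- water_equivalent_diameter(hu, mask, sp)
    # identity: dw^2 * pi / 4 = (meanHU/1000 + 1) * A
    expect_equal(dw$dw_cm^2 * pi / 4,
                 (dw$mean_hu / 1000 + 1) * dw$area_cm2, tolerance = 1e-12)
    expect_equal(dw$dw_cm, dw_pixel_oracle(hu, mask, sp), tolerance = 1e-9)
  }
})

test_that("air cells are Dw-invariant and tissue cells strictly increase Dw", {
  ph <- render_phantom(scene_library("pelvis", seed = 31))
  bm <- contour_body_new(ph$slice)
  base <- water_equivalent_diameter(ph$slice, bm)$dw_cm

  grown <- bm$mask
  air <- which(!grown & ph$slice$hu == -1000)[1:500]
  grown[air] <- TRUE
  expect_identical(water_equivalent_diameter(ph$slice$hu, grown,
                                             c(0.8, 0.8))$dw_cm, base)

  hu2 <- ph$slice$hu
  cell <- which(!bm$mask)[1]
  hu2[cell] <- 40
  more <- bm$mask; more[cell] <- TRUE
  expect_gt(water_equivalent_diameter(hu2, more, c(0.8, 0.8))$dw_cm, base)
})

test_that("mean_dw averages slices and rejects empty input", {
  mk <- function(d) structure(list(dw_cm = d), class = "dw_result")
  expect_equal(mean_dw(list(mk(20))), 20)
  expect_equal(mean_dw(list(mk(20), mk(30))), 25)
  expect_equal(mean_dw(rep(list(mk(24.56)), 100)), 24.56)
  expect_error(mean_dw(list()), "no Dw")
})

test_that("size conversion factor follows the exponential fits", {
  # f = 1 exactly where a * exp(-b * d) = 1, i.e. d = ln(a) / b
  expect_equal(size_conversion_factor(log(3.704369) / 0.03671937),
               1, tolerance = 1e-9)
  expect_equal(size_conversion_factor(log(1.874799) / 0.03871313,
                                      "head-16cm"), 1, tolerance = 1e-9)
  # strictly decreasing in Dw
  d <- seq(8, 45, by = 0.5)
  expect_true(all(diff(size_conversion_factor(d)) < 0))
  expect_error(size_conversion_factor(0), "positive")
  expect_warning(size_conversion_factor(60), "extrapolating")
  # user-supplied coefficient table wins
  tab <- data.frame(phantom_ref = "body-32cm", a = 2, b = 0.1)
  expect_equal(size_conversion_factor(10, coefficients = tab),
               2 * exp(-1), tolerance = 1e-12)
})

test_that("SSDE is the exact CTDIvol * f_size product", {
  expect_equal(ssde(10, 1.5), 15)
  expect_equal(ssde(10, 1.0), 10)
  expect_error(ssde(0, 1.5), "positive")
  # anti-monotone in Dw at fixed CTDIvol
  s <- ssde(10, size_conversion_factor(c(15, 25, 35)))
  expect_true(all(diff(s) < 0))
})

test_that("percentage differences follow (new - old) / old * 100", {
  expect_equal(percent_diff_dw(20, 20), 0)
  expect_equal(percent_diff_dw(27.81, 25.47), 9.1873, tolerance = 1e-4)
  expect_equal(percent_diff_dw(22, 11), 100)
  expect_error(percent_diff_dw(20, 0), "positive")
  expect_equal(percent_diff_ssde(21.47, 21.47), 0)
  expect_equal(percent_diff_ssde(15, 30), -50)
  expect_equal(percent_diff_ssde(25.20, 31.92), -21.0526, tolerance = 1e-4)
})
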