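test_that("maximum-intensity projection dominates every plane", {
  a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
  expect_identical(max_intensity_projection(a), a)
  proj <- max_intensity_projection(list(a, b))
  expect_true(all(proj >= a) && all(proj >= b))
  expect_identical(max_intensity_projection(list(a, a + 1)), a + 1)
  expect_error(max_intensity_projection(array(0, c(4, 4, 0))), "empty")
})

test_that("polygon rasterization follows the pixel-center even-odd rule", {
  # rectangle covering pixel centers x in 2..5, y in 1..3 -> 4 x 3 pixels
  roi <- roi_polygon(rbind(c(1.5, 0.5), c(5.5, 0.5), c(5.5, 3.5),
                           c(1.5, 3.5)))
  m <- rasterize_roi(roi, c(6, 8))
  expect_identical(sum(m), 12L)
  expect_true(m[2, 3] && m[4, 6])   # (x=2, y=1) and (x=5, y=3), 1-based
  expect_false(m[1, 2] || m[5, 6])
})

test_that("corrected mean intensity implements background subtraction exactly", {
  img <- matrix(10, 20, 20)
  img[5:10, 5:10] <- 50
  roi <- roi_polygon(rbind(c(3.5, 3.5), c(9.5, 3.5), c(9.5, 9.5),
                           c(3.5, 9.5)))
  bg <- roi_polygon(rbind(c(11.5, 11.5), c(18.5, 11.5), c(18.5, 18.5),
                          c(11.5, 18.5)))
  meas <- corrected_mean_intensity(img, roi, list(bg))
  expect_equal(meas$background_mean, 10)
  expect_equal(meas$corrected_per_area, 40)
  expect_equal(meas$corrected_per_area,
               (meas$roi_integrated - meas$background_mean * meas$roi_area) /
                 meas$roi_area)

  # uniform image: corrected intensity is exactly zero
  expect_equal(corrected_mean_intensity(matrix(7, 20, 20), roi,
                                        list(bg))$corrected_per_area, 0)
  # invariant to adding a constant to the whole image
  m2 <- corrected_mean_intensity(img + 123.4, roi, list(bg))
  expect_equal(m2$corrected_per_area, 40)
  # overlap is rejected
  expect_error(corrected_mean_intensity(img, roi, list(roi)), "overlap")
})

test_that("fold increase normalizes by the control pool mean", {
  expect_equal(fold_increase(40, list(10, 30)), 2)
  ctrl <- list(15, 25, 20)
  folds <- vapply(ctrl, fold_increase, numeric(1),
                  control_measurements = ctrl)
  expect_equal(mean(folds), 1)
  expect_error(fold_increase(40, list(0, 0)), "positive")
})

test_that("fractional area change matches its defining formula", {
  expect_equal(fractional_area_change(100, 40), 60)
  expect_equal(fractional_area_change(100, 100), 0)
  expect_warning(fac <- fractional_area_change(100, 120), "negative")
  expect_equal(fac, -20)
  expect_error(fractional_area_change(0, 10), "> 0")
  # invariant under uniform rescaling of both areas
  expect_equal(fractional_area_change(100 * 7, 40 * 7),
               fractional_area_change(100, 40))
})

test_that("area coverage is an exact ratio and monotone in the label", {
  reg <- matrix(FALSE, 20, 20); reg[1:10, 1:10] <- TRUE
  lab <- matrix(FALSE, 20, 20); lab[1:5, 1:5] <- TRUE
  expect_equal(area_coverage(lab, reg), 25)
  disj <- matrix(FALSE, 20, 20); disj[15:20, 15:20] <- TRUE
  expect_equal(area_coverage(disj, reg), 0)
  expect_equal(area_coverage(matrix(TRUE, 20, 20), reg), 100)
  # growing the label never shrinks coverage
  lab2 <- lab; lab2[1:7, 1:7] <- TRUE
  expect_gte(area_coverage(lab2, reg), area_coverage(lab, reg))
  expect_error(area_coverage(lab, matrix(FALSE, 20, 20)), "empty")
})

test_that("ventricular area normalization uses the control mean", {
  expect_equal(normalized_ventricular_area(80, c(90, 110)), 0.8)
  pool <- c(90, 100, 110)
  expect_equal(mean(vapply(pool, normalized_ventricular_area, numeric(1),
                           control_areas = pool)), 1)
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:4] <- TRUE
  expect_equal(normalized_ventricular_area(mask, c(40)), 0.5)
  expect_equal(normalized_ventricular_area(0, c(100)), 0)
  expect_error(normalized_ventricular_area(80, numeric(0)), "empty")
})
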