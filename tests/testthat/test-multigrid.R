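steady_stack <- function(kind, peak_px_frame, density = 0.012, seed = 5,
                         shape = c(128L, 256L), n_frames = 12L,
                         noise_sigma = 1) {
  acq <- acquisition_params(image_shape = shape, pixel_size = 1.75,
                            frame_interval = 40 / 3, n_frames = n_frames,
                            noise_sigma = noise_sigma, background_level = 10)
  u <- peak_px_frame * 1.75 / (40 / 3 / 1000)
  lum <- if (kind == "shear")
    wide_lumen(-0.875, (shape[1] - 0.5) * 1.75)
  else wide_lumen(-1e4, 1e4)
  fl <- flow_field(kind, peak_speed = u, lumen = lum)
  list(stack = generate_sequence(fl, acq, density = density, seed = seed),
       flow = fl, acq = acq)
}

test_that("uniform and zero flows are recovered to within a twentieth of a pixel", {
  # noise-free: the pattern shift is exact, so recovery is too
  s <- steady_stack("uniform", 3, noise_sigma = 0)
  al <- cycle_alignment(Inf, 12)
  f <- multigrid_piv(s$stack, al)
  expect_gt(mean(f$valid), 0.9)
  expect_lt(max(abs(f$u[f$valid] - 3)), 0.1)
  expect_lt(max(abs(f$v[f$valid])), 0.1)

  s0 <- steady_stack("uniform", 0, n_frames = 6L, noise_sigma = 0)
  f0 <- multigrid_piv(s0$stack, cycle_alignment(Inf, 6))
  expect_lt(max(abs(f0$u[f0$valid])), 0.05)
  expect_lt(max(abs(f0$v[f0$valid])), 0.05)
})

test_that("unit conversion and vector spacing match the calibration exactly", {
  s <- steady_stack("uniform", 2, shape = c(128L, 160L), n_frames = 6L)
  f <- multigrid_piv(s$stack, cycle_alignment(Inf, 6))
  expect_identical(f$u_um_s,
                   px_frame_to_um_s(f$u, f$pixel_size, f$frame_interval))
  expect_identical(f$v_um_s,
                   px_frame_to_um_s(f$v, f$pixel_size, f$frame_interval))
  expect_identical(f$spacing * f$pixel_size, 7)   # 4 px at 1.75 um/px
})

test_that("invalid schedules and undersized frames are rejected", {
  s <- steady_stack("uniform", 1, shape = c(128L, 160L), n_frames = 4L)
  al <- cycle_alignment(Inf, 4)
  expect_error(multigrid_piv(s$stack, al,
                             schedule = list(c(16L, 4L), c(48L, 24L))),
               "non-increasing")
  expect_error(multigrid_piv(s$stack, al, schedule = list()), "non-empty")
  tiny <- frame_stack(array(runif(40 * 40 * 4), c(40, 40, 4)), 1.75, 10)
  expect_error(multigrid_piv(tiny, al), "too small")
})

test_that("the normalized median test flags and repairs constructed outliers", {
  s <- steady_stack("uniform", 2, shape = c(128L, 160L), n_frames = 6L)
  f <- multigrid_piv(s$stack, cycle_alignment(Inf, 6))
  # corrupt one interior vector
  f$u[4, 5, 1] <- 9; f$v[4, 5, 1] <- -9
  fv <- validate_vectors(f)
  expect_false(fv$valid[4, 5, 1])
  expect_true(fv$replaced[4, 5, 1])
  expect_lt(abs(fv$u[4, 5, 1] - 2), 0.2)   # neighbor median
  # an all-identical field has zero median residual: nothing flagged
  fu <- f
  fu$u[] <- 2; fu$v[] <- 0; fu$valid[] <- TRUE; fu$replaced[] <- FALSE
  expect_equal(sum(!validate_vectors(fu)$valid), 0)
})

test_that("a smooth interior shear passes validation unflagged", {
  s <- steady_stack("shear", 6)
  f <- multigrid_piv(s$stack, cycle_alignment(Inf, 12))
  inner <- f$valid[3:(length(f$y) - 2), 3:(length(f$x) - 2), 1]
  expect_gt(mean(inner), 0.98)
})

test_that("multigrid refinement recovers a linear shear gradient", {
  s <- steady_stack("shear", 6)
  f <- multigrid_piv(s$stack, cycle_alignment(Inf, 12), keep_passes = TRUE)
  g_true <- 6 / (dim(s$stack$frames)[1] - 1)
  d <- expand.grid(y = f$y, x = f$x)
  ok <- as.vector(f$valid[, , 1])
  fit <- lm(as.vector(f$u[, , 1])[ok] ~ d$y[ok])
  expect_lt(abs(coef(fit)[2] - g_true) / g_true, 0.05)

  rmse <- vapply(f$passes, function(fp) {
    dd <- expand.grid(y = fp$y, x = fp$x)
    tru <- true_displacement(s$stack, dd$x, dd$y, 1)
    okp <- as.vector(fp$valid[, , 1])
    sqrt(mean((as.vector(fp$u[, , 1])[okp] - tru[okp, 1])^2 +
              (as.vector(fp$v[, , 1])[okp] - tru[okp, 2])^2))
  }, numeric(1))
  expect_lte(rmse[length(rmse)], rmse[1])
})
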