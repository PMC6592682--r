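test_that("particle clouds are Poisson-seeded, uniform and deterministic", {
  fov <- c(0, 100, 0, 50)
  expect_identical(length(make_particle_cloud(0, fov, seed = 1)$x), 0L)
  expect_error(make_particle_cloud(-1, fov), "density")

  c1 <- make_particle_cloud(0.05, fov, seed = 9)
  c2 <- make_particle_cloud(0.05, fov, seed = 9)
  expect_identical(c1, c2)

  # mean count over many seeds within 3 s.e. of density * area
  d <- 0.02; area <- 100 * 50
  counts <- vapply(1:400, function(s)
    length(make_particle_cloud(d, fov, seed = s)$x), numeric(1))
  se <- sqrt(d * area / 400)
  expect_lt(abs(mean(counts) - d * area), 3 * se)
})

test_that("advection integrates analytic fields exactly at their fixed points", {
  fov <- c(0, 200, 0, 100)
  cl <- make_particle_cloud(0.02, fov, seed = 3)

  still <- flow_field("uniform", peak_speed = 0)
  expect_equal(advect(cl, still, 0, 0.05)$x, cl$x)

  uni <- flow_field("uniform", peak_speed = 100, lumen = wide_lumen(-1e4, 1e4))
  expect_equal(advect(cl, uni, 0, 0.01)$x, cl$x + 1.0, tolerance = 1e-12)
  expect_equal(advect(cl, uni, 0, 0.01)$y, cl$y)
  expect_error(advect(cl, uni, 0, 0), "dt")

  # poiseuille: wall particle unmoved, centerline shifted by peak * dt
  poi <- flow_field("poiseuille", peak_speed = 200,
                    lumen = wide_lumen(0, 100))
  probe <- cl; probe$x <- c(50, 50); probe$y <- c(0, 50)
  moved <- advect(probe, poi, 0, 0.01)
  expect_equal(moved$x[1], 50)                    # at the wall
  expect_equal(moved$x[2], 50 + 200 * 0.01)       # centerline
})

test_that("flow fields are periodic, lumen-bounded and finite", {
  fl <- ablated_flow(mean_speed = 250, period = 0.4,
                     lumen = c(0, 500, 20, 120))
  pts <- cbind(runif(50, 0, 500), runif(50, 20, 120))
  for (t in c(0.05, 0.21)) {
    v1 <- eval_flow(fl, pts, t)
    expect_true(all(is.finite(v1)))
    expect_equal(v1, eval_flow(fl, pts, t + fl$period), tolerance = 1e-12)
  }
  outside <- rbind(c(-10, 70), c(250, 10), c(250, 130))
  expect_true(all(eval_flow(fl, outside, 0.1) == 0))
  expect_equal(fl$retrograde_fraction, acos(1 / 3) / pi, tolerance = 1e-3)
})

test_that("rendering conserves particle mass and places peaks correctly", {
  acq <- acquisition_params(image_shape = c(32L, 32L), pixel_size = 1,
                            frame_interval = 10, n_frames = 2,
                            noise_sigma = 0, background_level = 5)
  # empty cloud -> constant background
  empty <- make_particle_cloud(0, c(0, 31, 0, 31), seed = 1)
  expect_true(all(render_frame(empty, acq) == 5))

  # single particle at a pixel center -> frame max there
  one <- empty; one$x <- 16; one$y <- 12
  one$diameter <- 3; one$brightness <- 50
  img <- render_frame(one, acq)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 13, col = 17))

  # total intensity minus background ~ sum of brightnesses (interior cloud)
  acq2 <- acquisition_params(image_shape = c(64L, 64L), pixel_size = 1,
                             frame_interval = 10, n_frames = 2,
                             noise_sigma = 0, background_level = 0)
  cl <- make_particle_cloud(0.05, c(15, 48, 15, 48), seed = 4,
                            diameter = 3)
  img2 <- render_frame(cl, acq2)
  expect_lt(abs(sum(img2) - sum(cl$brightness)) / sum(cl$brightness), 0.01)
})

test_that("generated sequences are periodic, stationary and deterministic", {
  acq <- acquisition_params(image_shape = c(64L, 128L), pixel_size = 1.75,
                            frame_interval = 40 / 3, n_frames = 90L,
                            noise_sigma = 0, background_level = 10)
  fl <- control_flow(mean_speed = 400, period = 0.4,
                     lumen = wide_lumen(15, 100))
  st <- generate_sequence(fl, acq, density = 0.01, seed = 3)
  # exact periodicity: period = 30 frames
  expect_identical(st$frames[, , 1], st$frames[, , 31])
  expect_identical(st$frames[, , 7], st$frames[, , 67])
  # determinism
  st2 <- generate_sequence(fl, acq, density = 0.01, seed = 3)
  expect_identical(st$frames, st2$frames)
  # stationary seeding
  counts <- st$n_particles_in_fov
  expect_lt(max(abs(counts - mean(counts))) / mean(counts), 0.10)
  # too-short movies are rejected, naming the period
  acq_short <- acquisition_params(image_shape = c(64L, 128L),
                                  pixel_size = 1.75, frame_interval = 40 / 3,
                                  n_frames = 40L, noise_sigma = 0)
  expect_error(generate_sequence(fl, acq_short, 0.01, 1), "0.4")
})

test_that("steady uniform movies translate rigidly between frames", {
  acq <- acquisition_params(image_shape = c(48L, 96L), pixel_size = 1,
                            frame_interval = 10, n_frames = 5L,
                            noise_sigma = 0, background_level = 0)
  u <- 2 / 0.01  # exactly 2 px/frame
  fl <- flow_field("uniform", peak_speed = u, lumen = wide_lumen(-1e4, 1e4))
  st <- generate_sequence(fl, acq, density = 0.02, seed = 8)
  a <- st$frames[, 10:70, 1]
  b <- st$frames[, 12:72, 2]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("oscillatory ground truth reverses sign within each cycle", {
  acq <- acquisition_params(image_shape = c(64L, 128L), pixel_size = 1.75,
                            frame_interval = 40 / 3, n_frames = 90L,
                            noise_sigma = 0)
  fl <- ablated_flow(mean_speed = 250, period = 0.4,
                     lumen = wide_lumen(0, 63 * 1.75))
  st <- generate_sequence(fl, acq, density = 0.005, seed = 2)
  dx <- vapply(1:30, function(k)
    true_displacement(st, 64, 31.5, k)[1, 1], numeric(1))
  expect_true(any(dx > 0) && any(dx < 0))
})

test_that("waveform construction enforces the regime definitions", {
  w <- make_waveform("control", 2, 1, 64)
  expect_gt(min(w$Q), 0)
  wa <- make_waveform("ablated", 1, 3, 64)
  expect_lt(min(wa$Q), 0)
  expect_error(make_waveform("control", 2, 3, 64), "mean_flow")
  expect_error(make_waveform("ablated", 3, 1, 64), "mean_flow")
  expect_error(make_waveform("control", 2, 1, 3), "n_samples")
  # analytic FHI = amplitude / mean by construction
  expect_equal(fundamental_harmonic_index(w)$FHI, 0.5, tolerance = 1e-12)
  expect_equal(fundamental_harmonic_index(wa)$FHI, 3, tolerance = 1e-12)
})
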