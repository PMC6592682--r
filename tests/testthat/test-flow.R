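test_that("cross-sections carry a unit normal perpendicular to the line", {
  s <- cross_section(c(10, 80), c(10, 10))
  expect_equal(sqrt(sum(s$normal^2)), 1)
  expect_equal(sum(s$normal * s$tangent), 0)
  expect_equal(cross_section(c(0, 0), c(0, 10))$normal, c(1, 0))
  expect_equal(cross_section(c(0, 0), c(0, 10), flip_normal = TRUE)$normal,
               c(-1, 0))
  expect_error(cross_section(c(1, 1), c(1, 1)), "distinct")
})

test_that("velocity sampling is bilinear-exact and guards its domain", {
  uni <- flow_field("uniform", peak_speed = 100, lumen = wide_lumen(-1e4, 1e4))
  f <- analytic_velocity_field(uni, c(128, 128))
  smp <- sample_velocity(f, cross_section(c(100, 30), c(100, 180)), 1)
  expect_true(all(abs(smp$u - 100) < 1e-10))
  expect_true(all(abs(smp$v) < 1e-12))

  # linear-in-y field reproduced exactly between nodes
  sh <- flow_field("shear", peak_speed = 100,
                   lumen = wide_lumen(-0.875 * 1, 222.25))
  fs <- analytic_velocity_field(sh, c(128, 128))
  smp2 <- sample_velocity(fs, cross_section(c(100, 20), c(100, 200), dl = 3), 1)
  ramp <- (smp2$y - sh$lumen[3]) / (sh$lumen[4] - sh$lumen[3]) * 100
  expect_lt(max(abs(smp2$u - ramp)), 1e-9)

  expect_error(sample_velocity(f, cross_section(c(500, 0), c(500, 100)), 1),
               "outside")
  expect_error(sample_velocity(f, cross_section(c(100, 0), c(100, 100)), 99),
               "phase bin")
})

test_that("sections over invalid vectors are rejected as uncovered", {
  uni <- flow_field("uniform", peak_speed = 100, lumen = wide_lumen(-1e4, 1e4))
  f <- analytic_velocity_field(uni, c(128, 128))
  f$valid[, , 1] <- FALSE
  f$valid[1:8, , 1] <- TRUE
  expect_error(sample_velocity(f, cross_section(c(100, 30), c(100, 180)), 1),
               "insufficiently covered")
})

test_that("flow rate reproduces closed-form integrals", {
  uni <- flow_field("uniform", peak_speed = 100, lumen = wide_lumen(-1e4, 1e4))
  f <- analytic_velocity_field(uni, c(128, 128))
  vsec <- cross_section(c(100, 30), c(100, 180))
  q <- flow_rate(f, vsec)
  expect_equal(q$Q, 100, tolerance = 1e-12)
  expect_equal(q$Q_raw, 100 * q$L_included, tolerance = 1e-9)

  # parallel flow contributes nothing across a streamwise section
  hsec <- cross_section(c(50, 100), c(170, 100))
  expect_equal(flow_rate(f, hsec)$Q, 0, tolerance = 1e-12)

  # reversing the section negates the raw integral exactly
  q2 <- flow_rate(f, cross_section(c(100, 180), c(100, 30)))
  expect_identical(q$Q_raw, -q2$Q_raw)

  # Poiseuille: mean normal velocity = (2/3) v_max at dl = lumen / 50
  poi <- flow_field("poiseuille", peak_speed = 300,
                    lumen = wide_lumen(0, 210))
  fp <- analytic_velocity_field(poi, c(128, 128), spacing = 1)
  qp <- flow_rate(fp, cross_section(c(100, 0), c(100, 210), dl = 210 / 50))
  expect_lt(abs(qp$Q - 200) / 200, 0.005)

  # conservation across parallel full-lumen sections
  qq <- flow_rate(fp, cross_section(c(150, 0), c(150, 210), dl = 210 / 50))
  expect_lt(abs(qq$Q - qp$Q) / abs(qp$Q), 0.02)

  # linearity in the field
  f2 <- f
  f2$u_um_s <- 3 * f$u_um_s; f2$v_um_s <- 3 * f$v_um_s
  expect_equal(flow_rate(f2, vsec)$Q, 3 * q$Q, tolerance = 1e-12)
})

test_that("profiles average sections and track the analytic waveform", {
  fl <- control_flow(mean_speed = 400, lumen = wide_lumen(0, 210))
  f <- analytic_velocity_field(fl, c(128, 128), spacing = 2,
                               n_phase_bins = 30)
  secs <- lapply(c(60, 100, 140), function(x)
    cross_section(c(x, 10), c(x, 200)))
  prof <- suppressWarnings(flow_profile(f, secs))
  one <- suppressWarnings(flow_profile(f, secs[2]))
  # identical flow across x: multi-section average equals a single section
  expect_equal(prof$Q, one$Q, tolerance = 1e-9)
  # waveform shape: Q(t) proportional to mean + amp * cos(2 pi phase)
  shape <- 1 + 0.5 * cos(2 * pi * prof$phase)
  fitted <- shape * mean(prof$Q) / mean(shape)
  expect_lt(sqrt(mean((prof$Q - fitted)^2)) / mean(prof$Q), 0.01)

  h <- fundamental_harmonic_index(prof)
  expect_equal(h$FHI, 0.5, tolerance = 1e-6)

  # a region of zero flow gives an all-zero profile
  qz <- control_flow(mean_speed = 200, lumen = wide_lumen(0, 50))
  fz <- analytic_velocity_field(qz, c(128, 128), n_phase_bins = 30)
  pz <- suppressWarnings(flow_profile(fz,
    lapply(c(80, 100, 120), function(x)
      cross_section(c(x, 150), c(x, 210)))))   # outside the lumen
  expect_true(all(pz$Q == 0))
})

test_that("FHI closed forms, invariances and failure modes hold", {
  phase <- (0:63) / 64
  mk <- function(Q) cardiopiv:::new_flow_profile(Q, phase)
  h <- fundamental_harmonic_index(mk(2 + cos(2 * pi * phase)))
  expect_equal(h$Q0, 2, tolerance = 1e-9)
  expect_equal(h$Q1, 1, tolerance = 1e-9)
  expect_equal(h$FHI, 0.5, tolerance = 1e-9)

  expect_equal(fundamental_harmonic_index(mk(rep(5, 64)))$FHI, 0)

  base <- 1.3 + 0.8 * cos(2 * pi * phase + 0.7) +
    0.2 * cos(6 * pi * phase)
  h0 <- fundamental_harmonic_index(mk(base))
  hs <- fundamental_harmonic_index(mk(17.3 * base))
  expect_equal(hs$FHI, h0$FHI, tolerance = 1e-9)
  rolled <- mk(base[c(21:64, 1:20)])
  expect_equal(fundamental_harmonic_index(rolled)$FHI, h0$FHI,
               tolerance = 1e-9)

  expect_error(fundamental_harmonic_index(mk(sin(2 * pi * phase))),
               "undefined FHI")
})
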