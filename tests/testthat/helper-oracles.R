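# Independent oracles and small fixture builders used across the suite.

# brute-force zero-mean normalized cross-correlation over all lags
naive_zncc <- function(A, B, r) {
  w <- nrow(A)
  side <- 2 * r + 1
  out <- matrix(0, side, side)
  for (dx in -r:r) for (dy in -r:r) {
    Bd <- B[(r + dy + 1):(r + dy + w), (r + dx + 1):(r + dx + w)]
    if (stats::sd(A) < 1e-12 || stats::sd(Bd) < 1e-12) next
    out[dy + r + 1, dx + r + 1] <- stats::cor(as.vector(A), as.vector(Bd))
  }
  out
}

# search region of frame_b matching correlate_window_pair's extraction
extract_region <- function(frame, center, w, r) {
  h <- w %/% 2
  cx <- center[1]; cy <- center[2]
  list(A = frame[(cy - h + 1):(cy + w - h), (cx - h + 1):(cx + w - h)],
       B = frame[(cy - h - r + 1):(cy + w - h + r),
                 (cx - h - r + 1):(cx + w - h + r)])
}

# channel lumen with walls in y only; x extends far beyond the FOV so the
# margin band keeps feeding tracers
wide_lumen <- function(y0, y1) c(-1e4, 1e4, y0, y1)

# render a noise-free (or noisy) frame pair with a known uniform shift
shifted_pair <- function(shift_px, density = 0.02, noise_sigma = 0,
                         seed = 1, shape = c(64L, 128L),
                         pixel_size = 1.75) {
  acq <- acquisition_params(image_shape = shape, pixel_size = pixel_size,
                            frame_interval = 10, n_frames = 2,
                            noise_sigma = noise_sigma, background_level = 10)
  fov <- cardiopiv:::fov_um(acq)
  cl <- make_particle_cloud(density, fov, seed = seed, margin = 30)
  f1 <- render_frame(cl, acq, seed = 2 * seed)
  if (shift_px > 0) {
    fl <- flow_field("uniform", peak_speed = shift_px * pixel_size / 0.01,
                     lumen = wide_lumen(-1e4, 1e4))
    cl <- advect(cl, fl, 0, 0.01)
  }
  f2 <- render_frame(cl, acq, seed = 2 * seed + 1)
  list(f1 = f1, f2 = f2, acq = acq)
}

# single-particle peak amplitude over background, for SNR bookkeeping:
# a 5.25 um particle at 1.75 um/px has sigma 1.27 px and a central-pixel
# mass fraction of about 0.094, so brightness 100 gives peak ~ 9.4 and
# SNR 5 corresponds to noise_sigma ~ 1.9
snr5_sigma <- 1.9

# full synthetic recording -> alignment -> multigrid PIV -> FHI
recover_fhi <- function(regime, seed, n_frames = 300L,
                        shape = c(96L, 256L)) {
  acq <- acquisition_params(image_shape = shape, pixel_size = 1.75,
                            frame_interval = 40 / 3, n_frames = n_frames,
                            noise_sigma = 2, background_level = 10)
  fov <- cardiopiv:::fov_um(acq)
  lum <- wide_lumen(fov[3] + 0.15 * (fov[4] - fov[3]),
                    fov[3] + 0.85 * (fov[4] - fov[3]))
  fl <- if (regime == "control") control_flow(lumen = lum)
        else ablated_flow(lumen = lum)
  st <- generate_sequence(fl, acq, density = 0.01, seed = seed)
  al <- align_cycles(st)
  mask <- lumen_core_mask(fl, acq$pixel_size)
  f <- multigrid_piv(st, al, mask = mask)
  gx <- range(f$x) * acq$pixel_size
  gy <- c(max(min(f$y) * acq$pixel_size, mask[3] * acq$pixel_size + 7),
          min(max(f$y) * acq$pixel_size, mask[4] * acq$pixel_size - 7))
  secs <- lapply(gx[1] + c(0.35, 0.5, 0.65) * diff(gx), function(x)
    cross_section(c(x, gy[1]), c(x, gy[2]), pixel_size = acq$pixel_size,
                  label = "ventricle"))
  prof <- suppressWarnings(flow_profile(f, secs))
  h <- fundamental_harmonic_index(prof)
  list(fhi = h$FHI, true_fhi = analytic_fhi(fl), period = al$period,
       harmonic = h)
}
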