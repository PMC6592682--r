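#' Acquisition parameters for synthetic movies
#'
#' Defaults mirror a confocal resonance-scanner recording of circulating
#' labeled red blood cells: 512 x 128 px frames, 1.75 um/px, 75 frames per
#' second (40/3 ms per frame, so a 0.4 s cardiac period spans 30 frames)
#' and 500 frames (about 17 cycles).
#'
#' @param image_shape `c(height_px, width_px)`.
#' @param pixel_size um per pixel.
#' @param frame_interval ms per frame.
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma standard deviation of additive Gaussian sensor noise
#'   (intensity units).
#' @param background_level constant background offset (intensity units).
#' @return an `acquisition_params` object.
#' @export
acquisition_params <- function(image_shape = c(128L, 512L),
                               pixel_size = 1.75,
                               frame_interval = 40 / 3,
                               n_frames = 500L,
                               noise_sigma = 2,
                               background_level = 10) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  stopifnot(noise_sigma >= 0, background_level >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
                 background_level = background_level),
            class = "acquisition_params")
}

fov_um <- function(acq) {
  # field of view in um; pixel centers sit at 0 .. (n-1) * pixel_size
  c(xmin = -0.5 * acq$pixel_size,
    xmax = (acq$image_shape[2] - 0.5) * acq$pixel_size,
    ymin = -0.5 * acq$pixel_size,
    ymax = (acq$image_shape[1] - 0.5) * acq$pixel_size)
}

#' Seed a random particle cloud
#'
#' Particle count is Poisson with mean `density * area`, where the area is
#' the field of view expanded by `margin` on the left and right (the
#' margin band feeds particles that advect into view).  Positions are
#' uniform; the draw is deterministic given `seed`.
#'
#' @param density particles per um^2 (>= 0).
#' @param fov `c(xmin, xmax, ymin, ymax)` in um.
#' @param seed integer seed.
#' @param margin extra band in um added on the x (flow) axis.
#' @param diameter particle image diameter in um (rendered Gaussian sigma
#'   is `diameter / 2.355`, i.e. diameter is the FWHM).
#' @param brightness total intensity mass per particle.
#' @return a `particle_cloud` with positions in um.
#' @export
make_particle_cloud <- function(density, fov, seed = 1L, margin = 0,
                                diameter = 5.25, brightness = 100) {
  if (density < 0) stop("'density' must be >= 0")
  stopifnot(length(fov) == 4L, fov[2] > fov[1], fov[4] > fov[3])
  xlim <- c(fov[1] - margin, fov[2] + margin)
  area <- diff(xlim) * (fov[4] - fov[3])
  with_seed(seed, {
    n <- rpois(1L, density * area)
    structure(list(x = runif(n, xlim[1], xlim[2]),
                   y = runif(n, fov[3], fov[4]),
                   diameter = rep_len(diameter, n),
                   brightness = rep_len(brightness, n),
                   fov = as.numeric(fov), margin = margin,
                   seed = as.integer(seed)),
              class = "particle_cloud")
  })
}

#' Advect a particle cloud through a flow field
#'
#' Positions are advanced by fixed-step fourth-order Runge-Kutta
#' integration of the flow, with step size at most `dt / 4`.  Particles
#' leaving the margin band are recycled at the inflow edge (periodic wrap
#' along x), keeping the seeding density stationary.
#'
#' @param cloud a [make_particle_cloud()] cloud.
#' @param flow a [flow_field()].
#' @param t0 start time, s.
#' @param dt duration, s (> 0).
#' @param recycle wrap particles that exit the margin band (default TRUE).
#' @return the advected `particle_cloud`.
#' @export
advect <- function(cloud, flow, t0, dt, recycle = TRUE) {
  stopifnot(inherits(cloud, "particle_cloud"), inherits(flow, "flow_field"))
  if (dt <= 0) stop("'dt' must be > 0")
  n_steps <- max(4L, ceiling(dt / (dt / 4)))
  h <- dt / n_steps
  x <- cloud$x; y <- cloud$y
  t <- t0
  for (s in seq_len(n_steps)) {
    k1 <- eval_flow(flow, cbind(x, y), t)
    k2 <- eval_flow(flow, cbind(x + h / 2 * k1[, 1], y + h / 2 * k1[, 2]),
                    t + h / 2)
    k3 <- eval_flow(flow, cbind(x + h / 2 * k2[, 1], y + h / 2 * k2[, 2]),
                    t + h / 2)
    k4 <- eval_flow(flow, cbind(x + h * k3[, 1], y + h * k3[, 2]), t + h)
    x <- x + h / 6 * (k1[, 1] + 2 * k2[, 1] + 2 * k3[, 1] + k4[, 1])
    y <- y + h / 6 * (k1[, 2] + 2 * k2[, 2] + 2 * k3[, 2] + k4[, 2])
    t <- t + h
  }
  if (recycle && cloud$margin > 0) {
    xlo <- cloud$fov[1] - cloud$margin
    width <- (cloud$fov[2] + cloud$margin) - xlo
    x <- xlo + (x - xlo) %% width
  }
  cloud$x <- x; cloud$y <- y
  cloud
}

#' Render a particle cloud into an intensity frame
#'
#' Each particle becomes an isotropic Gaussian spot (sigma =
#' diameter / 2.355) integrated exactly over pixel areas, on a constant
#' background, with optional additive zero-mean Gaussian noise; negative
#' intensities are clipped at zero.
#'
#' @param cloud a `particle_cloud` (positions in um).
#' @param acq an [acquisition_params()].
#' @param seed seed for the noise draw (ignored when `noise_sigma = 0`).
#' @return an `image_shape` matrix of intensities.
#' @export
render_frame <- function(cloud, acq, seed = 1L) {
  stopifnot(inherits(cloud, "particle_cloud"),
            inherits(acq, "acquisition_params"))
  H <- acq$image_shape[1]; W <- acq$image_shape[2]
  sigma_px <- mean(cloud$diameter) / 2.355 / acq$pixel_size
  img <- cpp_render(cloud$x / acq$pixel_size, cloud$y / acq$pixel_size,
                    cloud$brightness, sigma_px, H, W)
  img <- img + acq$background_level
  if (acq$noise_sigma > 0)
    img <- img + with_seed(seed,
      matrix(rnorm(H * W, sd = acq$noise_sigma), H, W))
  img[img < 0] <- 0
  img
}

#' A calibrated time-lapse image stack
#'
#' @param frames H x W x n array (or list of matrices) of intensity frames.
#' @param pixel_size um/px.
#' @param frame_interval ms/frame.
#' @param z_index optional plane label.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval, z_index = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3] >= 2)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, z_index = z_index),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px, %.3g um/px, %.3g ms/frame\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Generate a synthetic particle movie with analytic ground truth
#'
#' Renders a time-lapse of tracer particles advected by `flow`.  For
#' periodic (pulsatile) fields the particle configuration is evaluated at
#' the frame time modulo the period, so that in the absence of noise the
#' configuration is exactly period-periodic (frames one period apart are
#' identical when the period is an integer number of frames).  One
#' consequence is that the single consecutive-frame pair per cycle that
#' crosses the wrap is non-physical; the PIV stage detects and discards
#' such pairs through its ensemble peak-correlation floor.
#'
#' The returned stack carries the generating flow field, so the analytic
#' velocity (and per-frame true displacement) can be sampled on any grid
#' with [true_displacement()].
#'
#' @param flow a [flow_field()].
#' @param acq an [acquisition_params()]; for periodic flows the movie must
#'   span at least two periods.
#' @param density particle seeding density, particles/um^2.
#' @param seed integer master seed (cloud and per-frame noise derive from
#'   it).
#' @param periodic_tiling for periodic flows: if `TRUE` (default) frame
#'   times are taken modulo the period, giving exactly periodic particle
#'   configurations; if `FALSE` particles advect continuously through the
#'   whole movie (with inflow recycling), so frames one period apart show
#'   the same flow state sampled by fresh tracers — the situation ensemble
#'   correlation is designed for.
#' @return a `frame_stack` with extra fields `flow`, `cloud0`, `seed` and
#'   `n_particles_in_fov` (per-frame count, for seeding-stationarity
#'   checks).
#' @export
generate_sequence <- function(flow, acq, density = 0.01, seed = 1L,
                              periodic_tiling = TRUE) {
  stopifnot(inherits(flow, "flow_field"), inherits(acq, "acquisition_params"))
  dt <- acq$frame_interval / 1000
  n <- acq$n_frames
  periodic <- flow$kind %in% c("pulsatile_forward", "pulsatile_oscillatory")
  if (periodic && n * dt < 2 * flow$period)
    stop(sprintf(
      "movie spans %.3f s but must cover at least two periods (period = %.3f s)",
      n * dt, flow$period))
  fov <- fov_um(acq)
  margin <- if (periodic) flow$peak_speed * flow$period
            else max(20, 2 * flow$peak_speed * dt)
  cloud0 <- make_particle_cloud(density, fov, seed = seed, margin = margin)
  noise_seeds <- with_seed(seed + 1L, sample.int(2^30, n))

  H <- acq$image_shape[1]; W <- acq$image_shape[2]
  frames <- array(0, dim = c(H, W, n))
  counts <- integer(n)
  if (periodic && !periodic_tiling) {
    cloud <- cloud0
    for (k in seq_len(n)) {
      if (k > 1) cloud <- advect(cloud, flow, (k - 2) * dt, dt)
      frames[, , k] <- render_frame(cloud, acq, seed = noise_seeds[k])
      counts[k] <- sum(cloud$x >= fov[1] & cloud$x <= fov[2])
    }
  } else if (periodic) {
    tt <- ((seq_len(n) - 1) * dt) %% flow$period
    ord <- order(tt)
    cloud <- cloud0
    tcur <- 0
    for (k in ord) {
      if (tt[k] > tcur + 1e-12) {
        cloud <- advect(cloud, flow, tcur, tt[k] - tcur, recycle = FALSE)
        tcur <- tt[k]
      }
      frames[, , k] <- render_frame(cloud, acq, seed = noise_seeds[k])
      counts[k] <- sum(cloud$x >= fov[1] & cloud$x <= fov[2])
    }
  } else {
    cloud <- cloud0
    for (k in seq_len(n)) {
      if (k > 1) cloud <- advect(cloud, flow, (k - 2) * dt, dt)
      frames[, , k] <- render_frame(cloud, acq, seed = noise_seeds[k])
      counts[k] <- sum(cloud$x >= fov[1] & cloud$x <= fov[2])
    }
  }
  out <- frame_stack(frames, acq$pixel_size, acq$frame_interval)
  out$flow <- flow
  out$acq <- acq
  out$cloud0 <- cloud0
  out$seed <- as.integer(seed)
  out$n_particles_in_fov <- counts
  out
}

#' True particle-pattern displacement between consecutive frames
#'
#' Integrates the generating flow field from the time of frame `frame` to
#' frame `frame + 1` at the requested pixel positions, returning the
#' displacement in px — the quantity a perfect PIV estimator would report.
#' Only available for stacks made by [generate_sequence()].
#'
#' @param stack a synthetic `frame_stack`.
#' @param x_px,y_px positions in pixels (0-based, vectors of equal length).
#' @param frame index of the first frame of the pair (1-based).
#' @return n x 2 matrix of displacements (dx, dy) in px.
#' @export
true_displacement <- function(stack, x_px, y_px, frame = 1L) {
  if (is.null(stack$flow)) stop("stack carries no ground-truth flow field")
  dt <- stack$frame_interval / 1000
  flow <- stack$flow
  t0 <- (frame - 1) * dt
  periodic <- flow$kind %in% c("pulsatile_forward", "pulsatile_oscillatory")
  if (periodic) t0 <- t0 %% flow$period
  xy <- cbind(x_px, y_px) * stack$pixel_size
  cl <- structure(list(x = xy[, 1], y = xy[, 2],
                       diameter = 1, brightness = 1,
                       fov = c(range(xy[, 1]) + c(-1, 1),
                               range(xy[, 2]) + c(-1, 1)),
                       margin = 0, seed = 0L),
                  class = "particle_cloud")
  cl2 <- advect(cl, flow, t0, dt, recycle = FALSE)
  cbind(dx = (cl2$x - cl$x), dy = (cl2$y - cl$y)) / stack$pixel_size
}
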