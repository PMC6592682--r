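#' Prescribed analytic flow fields
#'
#' Defines the 2-D velocity fields used by the synthetic movie generator.
#' All fields are separable, `v(x, y, t) = (s(y) * f(t), 0)`, confined to an
#' axis-aligned lumen (a straight channel segment standing in for a cardiac
#' chamber cross-section); outside the lumen the velocity is exactly zero.
#'
#' Kinds:
#' \describe{
#'   \item{uniform}{plug flow, `s = 1`, steady.}
#'   \item{shear}{linear ramp from 0 at the lower lumen wall to
#'     `peak_speed` at the upper wall, steady.}
#'   \item{poiseuille}{parabolic profile, `peak_speed` on the centerline,
#'     zero at the walls, steady.}
#'   \item{pulsatile_forward}{parabolic profile modulated in time by
#'     `f(t) = mean_speed + sum(amp_h * cos(2*pi*h*t/period + phase_h))`
#'     with the oscillation amplitude below the mean, so flow never
#'     reverses ("control"-like regime).}
#'   \item{pulsatile_oscillatory}{same form with amplitude above the mean,
#'     so part of each cycle is retrograde ("ablated"-like regime).}
#' }
#'
#' @param kind one of the field kinds above.
#' @param peak_speed maximum speed in um/s (steady kinds).
#' @param mean_speed time-averaged centerline speed in um/s (pulsatile
#'   kinds).
#' @param period cycle period in seconds (pulsatile kinds; the field is
#'   exactly periodic, `v(x, t) = v(x, t + period)`).
#' @param harmonics list of `c(harmonic_index, amplitude_um_s, phase_rad)`
#'   triples; defaults to a single fundamental with amplitude
#'   `0.5 * mean_speed` (forward) or `3 * mean_speed` (oscillatory).
#' @param lumen lumen bounds `c(xmin, xmax, ymin, ymax)` in um, or `NULL`
#'   for an unbounded field.
#' @return an object of class `flow_field`.
#' @examples
#' f <- flow_field("poiseuille", peak_speed = 500,
#'                 lumen = c(0, 800, 20, 120))
#' eval_flow(f, cbind(400, 70), 0)   # centerline: (500, 0)
#' @export
flow_field <- function(kind = c("uniform", "shear", "poiseuille",
                                "pulsatile_forward", "pulsatile_oscillatory"),
                       peak_speed = NULL, mean_speed = NULL,
                       period = 0.4, harmonics = NULL, lumen = NULL) {
  kind <- match.arg(kind)
  stopifnot_scalar(period, "period", positive = TRUE)
  if (!is.null(lumen)) {
    stopifnot(is.numeric(lumen), length(lumen) == 4L,
              lumen[2] > lumen[1], lumen[4] > lumen[3])
  }
  pulsatile <- kind %in% c("pulsatile_forward", "pulsatile_oscillatory")
  if (pulsatile) {
    stopifnot_scalar(mean_speed, "mean_speed", positive = TRUE)
    if (is.null(harmonics)) {
      amp <- if (kind == "pulsatile_forward") 0.5 * mean_speed
             else 3 * mean_speed
      harmonics <- list(c(1, amp, 0))
    }
    harm <- do.call(rbind, lapply(harmonics, function(h) {
      stopifnot(length(h) == 3L, h[1] >= 1, h[2] >= 0)
      h
    }))
    tt <- seq(0, period, length.out = 2048L)
    ft <- waveform_eval(mean_speed, harm, period, tt)
    peak_speed <- max(abs(ft))
    retro <- mean(ft < 0)
    if (kind == "pulsatile_forward" && retro > 0)
      stop("pulsatile_forward waveform reverses; reduce harmonic amplitudes")
    if (kind == "pulsatile_oscillatory" && retro == 0)
      warning("pulsatile_oscillatory waveform never reverses")
  } else {
    stopifnot_scalar(peak_speed, "peak_speed")
    if (peak_speed < 0) stop("'peak_speed' must be >= 0")
    harm <- NULL
    retro <- 0
  }
  structure(list(kind = kind, peak_speed = peak_speed,
                 mean_speed = mean_speed, period = period,
                 harmonics = harm, lumen = lumen,
                 retrograde_fraction = retro),
            class = "flow_field")
}

waveform_eval <- function(mean_speed, harm, period, t) {
  f <- rep(mean_speed, length(t))
  if (!is.null(harm))
    for (r in seq_len(nrow(harm)))
      f <- f + harm[r, 2] * cos(2 * pi * harm[r, 1] * t / period + harm[r, 3])
  f
}

#' Convenience constructors for the two hemodynamic regimes
#'
#' `control_flow()` builds a forward pulsatile field whose flow never
#' reverses (single fundamental harmonic, amplitude half the mean, analytic
#' FHI = 0.5).  `ablated_flow()` builds an oscillatory field with the
#' fundamental amplitude three times the mean, so flow reverses during
#' about 40 % of each cycle (analytic FHI = 3).
#'
#' @param mean_speed time-averaged centerline speed, um/s.
#' @param period cardiac period in seconds.
#' @param lumen lumen bounds `c(xmin, xmax, ymin, ymax)` in um.
#' @return a `flow_field`.
#' @export
control_flow <- function(mean_speed = 400, period = 0.4, lumen = NULL) {
  flow_field("pulsatile_forward", mean_speed = mean_speed, period = period,
             lumen = lumen)
}

#' @rdname control_flow
#' @export
ablated_flow <- function(mean_speed = 250, period = 0.4, lumen = NULL) {
  flow_field("pulsatile_oscillatory", mean_speed = mean_speed,
             period = period, lumen = lumen)
}

#' Evaluate a flow field
#'
#' @param flow a [flow_field()].
#' @param xy n x 2 matrix of positions in um.
#' @param t time in seconds (scalar).
#' @return n x 2 matrix of velocities in um/s (zero outside the lumen).
#' @export
eval_flow <- function(flow, xy, t) {
  stopifnot(inherits(flow, "flow_field"))
  xy <- matrix(as.numeric(xy), ncol = 2L)
  x <- xy[, 1]; y <- xy[, 2]
  lum <- flow$lumen
  if (is.null(lum)) {
    inside <- rep(TRUE, length(x))
    y0 <- min(y, 0); y1 <- max(y, 1)
  } else {
    inside <- x >= lum[1] & x <= lum[2] & y >= lum[3] & y <= lum[4]
    y0 <- lum[3]; y1 <- lum[4]
  }
  s <- switch(flow$kind,
    uniform = rep(1, length(y)),
    shear = (y - y0) / (y1 - y0),
    {  # parabolic for poiseuille and both pulsatile kinds
      yc <- (y0 + y1) / 2; hh <- (y1 - y0) / 2
      1 - ((y - yc) / hh)^2
    })
  amp <- if (flow$kind %in% c("uniform", "shear", "poiseuille"))
    flow$peak_speed
  else
    waveform_eval(flow$mean_speed, flow$harmonics, flow$period,
                  t %% flow$period)
  u <- s * amp
  u[!inside] <- 0
  cbind(u = u, v = numeric(length(u)))
}

#' Analytic Fundamental Harmonic Index of a pulsatile field
#'
#' For the single-fundamental default waveforms this is exactly
#' `amplitude / mean_speed`; in general it is computed from the harmonic
#' table as `2|c1| / |c0|`.
#'
#' @param flow a pulsatile [flow_field()].
#' @return dimensionless FHI.
#' @export
analytic_fhi <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  if (is.null(flow$harmonics)) stop("field has no temporal harmonics")
  h1 <- flow$harmonics[flow$harmonics[, 1] == 1, , drop = FALSE]
  a1 <- if (nrow(h1)) h1[1, 2] else 0
  a1 / abs(flow$mean_speed)
}

#' Build an analytic single-harmonic flow waveform
#'
#' Returns one cycle of `Q(t) = mean_flow + osc_amplitude *
#' cos(2*pi*phase)` sampled at `n_samples` uniform phases.  The "control"
#' kind requires the oscillation amplitude to stay below the mean (flow
#' never reverses); "ablated" requires it to exceed the mean (sign-changing
#' flow).  The analytic FHI of either waveform is
#' `osc_amplitude / mean_flow` by construction.
#'
#' @param kind "control" or "ablated".
#' @param mean_flow time-averaged flow, um/s.
#' @param osc_amplitude fundamental amplitude, um/s.
#' @param n_samples samples per cycle (>= 4).
#' @return a `flow_profile` object (fields `Q`, `phase`).
#' @export
make_waveform <- function(kind = c("control", "ablated"), mean_flow,
                          osc_amplitude, n_samples = 64L) {
  kind <- match.arg(kind)
  stopifnot_scalar(mean_flow, "mean_flow", positive = TRUE)
  stopifnot_scalar(osc_amplitude, "osc_amplitude")
  if (n_samples < 4) stop("'n_samples' must be >= 4")
  if (kind == "control" && osc_amplitude >= mean_flow)
    stop("control waveform requires osc_amplitude < mean_flow")
  if (kind == "ablated" && osc_amplitude <= mean_flow)
    stop("ablated waveform requires osc_amplitude > mean_flow")
  phase <- (seq_len(n_samples) - 1) / n_samples
  new_flow_profile(Q = mean_flow + osc_amplitude * cos(2 * pi * phase),
                   phase = phase)
}

#' Sample an analytic flow field as a velocity field
#'
#' Evaluates a [flow_field()] on a regular pixel grid at the center time
#' of every phase bin, returning the same `velocity_field` structure that
#' [multigrid_piv()] produces (all vectors valid).  This is the ground
#' truth against which PIV output is judged, and lets the flow-rate and
#' FHI stages be exercised without any imaging.
#'
#' @param flow a [flow_field()].
#' @param image_shape `c(height_px, width_px)` extent of the grid.
#' @param pixel_size um/px.
#' @param frame_interval ms/frame (sets the px/frame values).
#' @param spacing grid spacing in px (default 4, i.e. 7 um at 1.75 um/px).
#' @param n_phase_bins phase bins over one period (1 for steady kinds).
#' @return a `velocity_field`.
#' @export
analytic_velocity_field <- function(flow, image_shape, pixel_size = 1.75,
                                    frame_interval = 40 / 3, spacing = 4L,
                                    n_phase_bins = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  steady <- flow$kind %in% c("uniform", "shear", "poiseuille")
  if (is.null(n_phase_bins))
    n_phase_bins <- if (steady) 1L
      else max(4L, round(flow$period / (frame_interval / 1000)))
  x <- seq.int(0L, image_shape[2] - 1L, by = spacing)
  y <- seq.int(0L, image_shape[1] - 1L, by = spacing)
  g <- expand.grid(x = x, y = y)
  shape <- c(length(y), length(x), n_phase_bins)
  u <- array(0, shape); v <- array(0, shape)
  for (b in seq_len(n_phase_bins)) {
    t <- if (steady) 0 else (b - 0.5) / n_phase_bins * flow$period
    uv <- eval_flow(flow, as.matrix(g) * pixel_size, t)
    u[, , b] <- matrix(uv[, 1], length(y), length(x), byrow = TRUE)
    v[, , b] <- matrix(uv[, 2], length(y), length(x), byrow = TRUE)
  }
  grid <- list(x = x, y = y, window_size = NA_integer_,
               spacing = as.integer(spacing))
  fld <- new_velocity_field(grid,
                            um_s_to_px_frame(u, pixel_size, frame_interval),
                            um_s_to_px_frame(v, pixel_size, frame_interval),
                            valid = array(TRUE, shape),
                            peak_ratio = array(Inf, shape),
                            peak_corr = array(1, shape),
                            pixel_size, frame_interval, pass_index = 0L)
  fld
}

new_flow_profile <- function(Q, phase, n_sections_averaged = 1L,
                             n_stacks = 1L, units = "um/s") {
  stopifnot(length(Q) == length(phase), length(Q) >= 4,
            all(diff(phase) > 0), all(phase >= 0 & phase < 1))
  structure(list(Q = as.numeric(Q), phase = as.numeric(phase),
                 units = units,
                 n_sections_averaged = n_sections_averaged,
                 n_stacks = n_stacks),
            class = "flow_profile")
}
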