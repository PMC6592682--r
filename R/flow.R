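#' A user-drawn cross-section line
#'
#' A directed line from `a` to `b` (um) with a unit normal obtained by
#' rotating the a-to-b direction 90 degrees counter-clockwise (so with
#' image coordinates, y down, a section drawn across a channel from the
#' lower to the upper wall has its normal pointing downstream).  Flow rate
#' is integrated at midpoint sample positions `s = dl/2, 3*dl/2, ...`
#' along the line, which makes the rectangle-rule sum and the included
#' length `n * dl` exactly consistent.
#'
#' @param a,b endpoints `c(x, y)` in um.
#' @param dl sample spacing in um; the conventional choice is 4 px, i.e.
#'   `4 * pixel_size` (7 um at 1.75 um/px), the default when a
#'   `pixel_size` is given.
#' @param pixel_size optional calibration used for the default `dl`.
#' @param label region tag ("ventricle", "AVC", "atrium", "other").
#' @param flip_normal reverse the normal (changes the sign of Q).
#' @return a `cross_section`.
#' @export
cross_section <- function(a, b, dl = NULL, pixel_size = 1.75,
                          label = "other", flip_normal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2L, length(b) == 2L)
  len <- sqrt(sum((b - a)^2))
  if (len <= 0) stop("'a' and 'b' must be distinct points")
  if (is.null(dl)) dl <- 4 * pixel_size
  stopifnot_scalar(dl, "dl", positive = TRUE)
  tang <- (b - a) / len
  nrm <- c(tang[2], -tang[1])          # 90 deg CCW in y-down image coords
  if (flip_normal) nrm <- -nrm
  structure(list(a = a, b = b, length = len, tangent = tang, normal = nrm,
                 dl = dl, label = label),
            class = "cross_section")
}

section_samples <- function(section) {
  ns <- floor(section$length / section$dl)
  if (ns < 1) stop("section shorter than one sample spacing 'dl'")
  s <- (seq_len(ns) - 0.5) * section$dl
  cbind(x = section$a[1] + s * section$tangent[1],
        y = section$a[2] + s * section$tangent[2])
}

#' Sample a velocity field along a cross-section
#'
#' Bilinearly interpolates the phase-bin velocity field onto the section's
#' midpoint sample positions.  Sample points whose four surrounding grid
#' nodes are not all usable (measured-valid or median-replaced) are
#' flagged and excluded from integration.
#'
#' @param field a `velocity_field` (from [multigrid_piv()]).
#' @param section a [cross_section()].
#' @param phase_bin bin index.
#' @return data frame with columns `x`, `y` (um), `u`, `v` (um/s),
#'   `included`.
#' @export
sample_velocity <- function(field, section, phase_bin = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(section, "cross_section"))
  nb <- dim(field$u)[3]
  if (phase_bin < 1 || phase_bin > nb)
    stop(sprintf("phase bin %d does not exist", phase_bin))
  pts <- section_samples(section)
  gx <- field$x * field$pixel_size      # grid coordinates in um
  gy <- field$y * field$pixel_size
  qx <- pts[, 1]; qy <- pts[, 2]
  if (any(qx < min(gx) - 1e-9) || any(qx > max(gx) + 1e-9) ||
      any(qy < min(gy) - 1e-9) || any(qy > max(gy) + 1e-9))
    stop("section extends outside the velocity-field extent")
  U <- field$u_um_s[, , phase_bin]; V <- field$v_um_s[, , phase_bin]
  usable <- (field$valid[, , phase_bin] | field$replaced[, , phase_bin]) &
    is.finite(U)
  Uz <- U; Uz[!usable] <- 0; Vz <- V; Vz[!usable] <- 0
  u <- bilinear(gx, gy, Uz, qx, qy)
  v <- bilinear(gx, gy, Vz, qx, qy)
  corner_ok <- bilinear(gx, gy, matrix(as.numeric(usable), nrow(U)), qx, qy)
  included <- corner_ok > 1 - 1e-9     # all four corners usable
  if (mean(included) < 0.5)
    stop("section insufficiently covered: more than 50% of samples excluded")
  data.frame(x = qx, y = qy, u = u, v = v, included = included)
}

#' Cross-sectional flow rate
#'
#' Discretizes `Q = integral of v . n dl` along the section with the
#' rectangle rule at midpoint samples, matching the discrete sum used with
#' hand-drawn lines (`dl` conventionally 4 px).  `Q_raw` (um^2/s in 2-D)
#' is the line integral itself; the headline `Q` is the length-normalized
#' mean normal velocity `Q_raw / L_included` (um/s), the quantity plotted
#' as "flow rate" in mm/s-style units.  The Fundamental Harmonic Index is
#' identical under either convention.
#'
#' @inheritParams sample_velocity
#' @return list with `Q` (um/s), `Q_raw` (um^2/s), `L_included` (um),
#'   `n_samples`, `n_included`.
#' @export
flow_rate <- function(field, section, phase_bin = 1L) {
  smp <- sample_velocity(field, section, phase_bin)
  inc <- smp$included
  vn <- smp$u[inc] * section$normal[1] + smp$v[inc] * section$normal[2]
  Q_raw <- sum(vn) * section$dl
  L <- sum(inc) * section$dl
  list(Q = Q_raw / L, Q_raw = Q_raw, L_included = L,
       n_samples = nrow(smp), n_included = sum(inc))
}

#' Phase-resolved flow profile averaged over sections
#'
#' Computes the flow rate at every cardiac phase bin for each section and
#' averages across sections (and, if `field` is a list of fields from
#' several z-stacks, across stacks with equal weight).  A section that
#' fails on more than 25 % of phase bins is dropped with a warning; phase
#' bins at which no section yields a value are omitted from the profile
#' (the FHI computation resamples the profile to a uniform phase grid).
#'
#' @param field a `velocity_field`, or a list of them (one per z-stack).
#' @param sections a list of [cross_section()]s (conventionally 3–5,
#'   drawn in at least two stacks).
#' @return a `flow_profile` with `Q` (um/s) and `phase` in `[0, 1)`.
#' @export
flow_profile <- function(field, sections) {
  if (inherits(field, "velocity_field")) field <- list(field)
  stopifnot(length(field) >= 1,
            all(vapply(field, inherits, logical(1), "velocity_field")))
  if (inherits(sections, "cross_section")) sections <- list(sections)
  if (!length(sections)) stop("at least one cross-section is required")
  if (length(sections) < 3 || length(sections) > 5)
    warning("three to five sections per region are conventional; got ",
            length(sections))
  if (length(field) < 2)
    warning("measurements from at least two stacks are conventional")
  nbin <- dim(field[[1]]$u)[3]
  Qmat <- matrix(NA_real_, nbin, 0)
  for (f in field) for (sec in sections) {
    q <- vapply(seq_len(nbin), function(b) {
      tryCatch(flow_rate(f, sec, b)$Q, error = function(e) NA_real_)
    }, numeric(1))
    if (mean(is.na(q)) > 0.25) {
      warning(sprintf("section '%s' dropped: failed on %.0f%% of phase bins",
                      sec$label, 100 * mean(is.na(q))))
      next
    }
    Qmat <- cbind(Qmat, q)
  }
  if (ncol(Qmat) == 0) stop("all sections dropped; no flow profile")
  Q <- rowMeans(Qmat, na.rm = TRUE)
  phase <- (seq_len(nbin) - 0.5) / nbin
  keep <- is.finite(Q)
  if (sum(keep) < 4) stop("fewer than four usable phase bins")
  new_flow_profile(Q[keep], phase[keep],
                   n_sections_averaged = length(sections),
                   n_stacks = length(field))
}

#' Fundamental Harmonic Index of a flow profile
#'
#' With DFT coefficients `c_m = (1/N) sum_k Q_k exp(-2 pi i k m / N)` of
#' the phase-ordered profile: `Q0 = Re(c_0)` (time-averaged flow),
#' `Q1 = 2 |c_1|` (amplitude of the fundamental harmonic, so a pure cosine
#' of amplitude A gives Q1 = A), and `FHI = Q1 / |Q0|`.  High FHI marks
#' oscillatory, sign-changing flow; FHI is invariant under positive
#' scaling and cyclic phase shifts.  Profiles with non-uniform phase
#' sampling are linearly resampled onto a uniform phase grid first.
#'
#' @param profile a `flow_profile` (from [flow_profile()] or
#'   [make_waveform()]).
#' @return a `harmonic_result`: `Q0`, `Q1`, `FHI`.
#' @export
fundamental_harmonic_index <- function(profile) {
  stopifnot(inherits(profile, "flow_profile"))
  Q <- profile$Q; ph <- profile$phase
  N <- length(Q)
  if (N < 4) stop("profile must contain at least four samples")
  # equal spacing suffices: a constant phase offset is a cyclic shift and
  # leaves Q0 and |c_1| unchanged
  uniform <- N >= 2 && max(abs(diff(ph) - 1 / N)) < 1e-9
  if (!uniform) {
    grid <- (seq_len(N) - 1) / N
    # periodic linear interpolation
    phx <- c(ph - 1, ph, ph + 1)
    Qx <- rep(Q, 3)
    Q <- approx(phx, Qx, xout = grid, rule = 2)$y
  }
  cm <- fft(Q) / N
  Q0 <- Re(cm[1])
  Q1 <- 2 * Mod(cm[2])
  if (abs(Q0) < 1e-9 * max(abs(Q)))
    stop("undefined FHI: near-zero mean flow")
  structure(list(Q0 = Q0, Q1 = Q1, FHI = Q1 / abs(Q0)),
            class = "harmonic_result")
}

#' @export
print.harmonic_result <- function(x, ...) {
  cat(sprintf("Q0 = %.4g, Q1 = %.4g, FHI = %.4g\n", x$Q0, x$Q1, x$FHI))
  invisible(x)
}
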