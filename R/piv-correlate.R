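#' Cross-correlate one interrogation window pair
#'
#' Computes the zero-mean normalized (Pearson) cross-correlation between a
#' `window_size` x `window_size` window of `frame_a` centered at `center`
#' and the matching window of `frame_b` displaced by `predictor_shift`
#' plus every integer lag within `search_radius`.  Values lie in
#' `[-1, 1]`; windows with zero intensity variance yield a degenerate
#' (all-zero) plane.
#'
#' Two equivalent backends are provided: `"direct"` (compiled direct
#' summation) and `"fft"` (FFT-accelerated numerator with integral-image
#' window sums); they agree to better than 1e-8.
#'
#' @param frame_a,frame_b intensity matrices of equal shape.
#' @param center window center `c(x, y)` in 0-based pixel coordinates
#'   (even window sizes cover pixels `c - w/2 .. c + w/2 - 1`).
#' @param window_size window side in px.
#' @param search_radius maximum absolute lag in px.
#' @param predictor_shift integer shift `c(dx, dy)` applied to the
#'   b-window before the lag search (window-offset PIV).
#' @param method `"direct"` or `"fft"`.
#' @return a `correlation_plane`: `values` (rows = dy, cols = dx, lag
#'   `(0,0)` at the center), `search_radius`, `predictor_shift`,
#'   `n_pairs_pooled`, `degenerate`.
#' @export
correlate_window_pair <- function(frame_a, frame_b, center, window_size,
                                  search_radius,
                                  predictor_shift = c(0L, 0L),
                                  method = c("direct", "fft")) {
  method <- match.arg(method)
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  w <- as.integer(window_size); r <- as.integer(search_radius)
  h <- w %/% 2L
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  px <- as.integer(round(predictor_shift[1]))
  py <- as.integer(round(predictor_shift[2]))
  H <- nrow(frame_a); W <- ncol(frame_a)
  a_ok <- cx - h >= 0 && cx + w - h - 1 <= W - 1 &&
          cy - h >= 0 && cy + w - h - 1 <= H - 1
  bx <- cx + px; by <- cy + py
  b_ok <- bx - h - r >= 0 && bx + w - h - 1 + r <= W - 1 &&
          by - h - r >= 0 && by + w - h - 1 + r <= H - 1
  if (!a_ok || !b_ok)
    stop("interrogation window (or its shifted search region) lies outside the frame")
  A <- frame_a[(cy - h + 1):(cy + w - h), (cx - h + 1):(cx + w - h)]
  B <- frame_b[(by - h - r + 1):(by + w - h + r),
               (bx - h - r + 1):(bx + w - h + r)]
  vals <- if (method == "direct") cpp_zncc_plane(A, B, r)
          else zncc_plane_fft(A, B, r)
  new_correlation_plane(vals, r, c(px, py), n_pairs_pooled = 1L,
                        center = c(cx, cy))
}

new_correlation_plane <- function(values, search_radius, predictor_shift,
                                  n_pairs_pooled, center = NULL) {
  structure(list(values = values, search_radius = search_radius,
                 predictor_shift = predictor_shift,
                 n_pairs_pooled = as.integer(n_pairs_pooled),
                 center = center,
                 degenerate = all(values == 0)),
            class = "correlation_plane")
}

# FFT-accelerated ZNCC: the cross-correlation numerator via FFT and the
# per-lag window sums via 2-D integral images.  Matches the direct sum to
# machine precision.
zncc_plane_fft <- function(A, B, radius) {
  w <- nrow(A); nb <- nrow(B); r <- radius
  n <- w * w
  A0 <- A - mean(A)
  ssa <- sum(A0^2)
  side <- 2L * r + 1L
  if (ssa <= 1e-12) return(matrix(0, side, side))
  Apad <- matrix(0, nb, nb)
  Apad[1:w, 1:w] <- A0
  # cross-correlation theorem: cc[s1+1, s2+1] = sum_ij A0[i,j] B[i+s1, j+s2]
  # and the lag (dy, dx) window starts at shift (r+dy, r+dx) in [0, 2r]
  cc <- Re(fft(fft(B) * Conj(fft(Apad)), inverse = TRUE)) / (nb * nb)
  numshift <- cc[1:(2 * r + 1), 1:(2 * r + 1), drop = FALSE]
  # integral images for the b-window mean/variance at each lag
  P1 <- rbind(0, cbind(0, t(apply(apply(B, 2, cumsum), 1, cumsum))))
  P2 <- rbind(0, cbind(0, t(apply(apply(B^2, 2, cumsum), 1, cumsum))))
  boxsum <- function(P, r0, c0)  # 0-based top-left, w x w box
    P[r0 + w + 1, c0 + w + 1] - P[r0 + 1, c0 + w + 1] -
    P[r0 + w + 1, c0 + 1] + P[r0 + 1, c0 + 1]
  plane <- matrix(0, side, side)
  for (dx in -r:r) for (dy in -r:r) {
    s1 <- boxsum(P1, r + dy, r + dx)
    s2 <- boxsum(P2, r + dy, r + dx)
    ssb <- s2 - s1 * s1 / n
    den <- ssa * ssb
    plane[dy + r + 1, dx + r + 1] <-
      if (den <= 1e-12) 0 else numshift[dy + r + 1, dx + r + 1] / sqrt(den)
  }
  plane
}

#' Locate the correlation peak with subpixel precision
#'
#' Finds the integer argmax of a correlation plane (ties broken toward the
#' smaller displacement magnitude, then lexicographically in `(dx, dy)`),
#' then refines it independently in x and y by a three-point Gaussian fit
#' (falling back to a parabolic fit when neighbors are non-positive).  The
#' peak ratio is the highest local maximum divided by the second-highest.
#'
#' @param plane a `correlation_plane` (or a bare lag matrix with lag
#'   `(0,0)` at the center).
#' @return list with `displacement` (`c(dx, dy)`, px, real-valued; the
#'   plane's predictor shift is *not* added), `peak_value`, `peak_ratio`,
#'   `border_limited` (peak on the search border, no subpixel fit).
#' @export
locate_peak <- function(plane) {
  vals <- if (inherits(plane, "correlation_plane")) plane$values else plane
  if (all(!is.finite(vals)) || all(vals == 0))
    stop("degenerate window: correlation plane carries no signal")
  side <- nrow(vals)
  r <- (side - 1L) %/% 2L
  m <- max(vals, na.rm = TRUE)
  tie <- which(vals >= m - 1e-15, arr.ind = TRUE)
  d <- cbind(dx = tie[, 2] - r - 1, dy = tie[, 1] - r - 1)
  o <- order(d[, 1]^2 + d[, 2]^2, d[, 1], d[, 2])
  iy <- tie[o[1], 1]; ix <- tie[o[1], 2]
  border <- iy == 1 || iy == side || ix == 1 || ix == side
  dx <- ix - r - 1; dy <- iy - r - 1
  # a perfect-correlation peak means the patterns match exactly at an
  # integer lag; any three-point refinement would only add spurious
  # offset from the asymmetric per-lag normalization
  if (!border && m < 1 - 1e-9) {
    dx <- dx + subpixel_offset(vals[iy, ix - 1], vals[iy, ix], vals[iy, ix + 1])
    dy <- dy + subpixel_offset(vals[iy - 1, ix], vals[iy, ix], vals[iy + 1, ix])
  }
  list(displacement = c(dx = dx, dy = dy), peak_value = m,
       peak_ratio = peak_ratio(vals), border_limited = border)
}

subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    den <- log(cm) - 2 * log(c0) + log(cp)
    if (den < 0) return(max(-0.5, min(0.5, 0.5 * (log(cm) - log(cp)) / den)))
  }
  den <- cm - 2 * c0 + cp
  if (den < 0) max(-0.5, min(0.5, 0.5 * (cm - cp) / den)) else 0
}

peak_ratio <- function(vals) {
  side <- nrow(vals)
  if (side < 3) return(Inf)
  loc <- matrix(TRUE, side, side)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  inner <- vals[2:(side - 1), 2:(side - 1)]
  ok <- matrix(TRUE, side - 2, side - 2)
  for (s in seq_len(nrow(shifts))) {
    if (shifts$dy[s] == 0 && shifts$dx[s] == 0) next
    nb <- vals[2:(side - 1) + shifts$dy[s], 2:(side - 1) + shifts$dx[s]]
    ok <- ok & inner >= nb
  }
  peaks <- sort(inner[ok], decreasing = TRUE)
  if (length(peaks) < 2 || peaks[2] <= 0) Inf else peaks[1] / peaks[2]
}

#' Regular grid of interrogation windows
#'
#' @param image_shape `c(height_px, width_px)` of the frames.
#' @param window_size window side, px.
#' @param spacing grid spacing, px (`<= window_size`: windows tile or
#'   overlap).
#' @param search_radius search margin reserved at the frame borders.
#' @param mask optional lumen mask: either bounds `c(xmin, xmax, ymin,
#'   ymax)` in px, or a function `(x_px, y_px) -> logical`; windows whose
#'   centers fall outside are excluded.
#' @return an `interrogation_grid`: `x`, `y` (axis center coordinates),
#'   `centers` (n x 2), `keep` (logical per grid node).
#' @export
interrogation_grid <- function(image_shape, window_size, spacing,
                               search_radius = 4L, mask = NULL) {
  if (spacing > window_size) stop("'spacing' must be <= 'window_size'")
  H <- image_shape[1]; W <- image_shape[2]
  h <- window_size %/% 2L
  lo <- h + search_radius
  hix <- W - h - search_radius; hiy <- H - h - search_radius
  if (hix < lo || hiy < lo)
    stop(sprintf("frame too small for %d px windows (+%d px search)",
                 window_size, search_radius))
  x <- seq.int(lo, hix, by = spacing)
  y <- seq.int(lo, hiy, by = spacing)
  g <- expand.grid(x = x, y = y)
  keep <- rep(TRUE, nrow(g))
  if (!is.null(mask)) {
    keep <- if (is.function(mask)) mask(g$x, g$y)
            else g$x >= mask[1] & g$x <= mask[2] &
                 g$y >= mask[3] & g$y <= mask[4]
  }
  structure(list(x = x, y = y, centers = as.matrix(g), keep = keep,
                 window_size = as.integer(window_size),
                 spacing = as.integer(spacing),
                 search_radius = as.integer(search_radius)),
            class = "interrogation_grid")
}

#' Ensemble-averaged correlation planes for one cardiac phase
#'
#' Pools the correlation planes of all consecutive-frame pairs whose first
#' frame falls in `phase_bin` (the same flow state sampled across all
#' cycles) by arithmetic averaging, window by window — the low-seeding
#' workhorse of ensemble micro-PIV.
#'
#' @param stack a [frame_stack()].
#' @param alignment a `cycle_alignment`.
#' @param grid an [interrogation_grid()].
#' @param phase_bin bin index.
#' @param predictor optional n x 2 integer matrix of per-window predictor
#'   shifts (defaults to zero).
#' @param pairs optional 2-column matrix of frame index pairs, overriding
#'   the alignment (e.g. to pool a chosen number of cycles).
#' @param stride frame-pairing stride (default 1: consecutive frames).
#' @return list of `correlation_plane` objects (one per kept grid window;
#'   windows clipped by the frame border have `NULL` entries).
#' @export
ensemble_correlation <- function(stack, alignment, grid, phase_bin = 1L,
                                 predictor = NULL, pairs = NULL,
                                 stride = 1L) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(grid, "interrogation_grid"))
  if (is.null(pairs)) {
    stopifnot(inherits(alignment, "cycle_alignment"))
    if (phase_bin < 1 || phase_bin > alignment$n_phase_bins)
      stop(sprintf("phase bin %d does not exist", phase_bin))
    pairs <- pairs_in_bin(alignment, phase_bin, stride)
    if (nrow(pairs) == 0)
      stop(sprintf("phase bin %d contains no frame pairs", phase_bin))
  }
  centers <- grid$centers[grid$keep, , drop = FALSE]
  if (is.null(predictor)) predictor <- matrix(0L, nrow(centers), 2L)
  res <- cpp_ensemble_planes(stack$frames, dim(stack$frames),
                             as.integer(pairs[, 1]), as.integer(pairs[, 2]),
                             storage_int(centers), storage_int(predictor),
                             grid$window_size, grid$search_radius)
  side <- 2L * grid$search_radius + 1L
  lapply(seq_len(nrow(centers)), function(i) {
    if (!res$inside[i]) return(NULL)
    new_correlation_plane(matrix(res$planes[, i], side, side),
                          grid$search_radius, predictor[i, ],
                          n_pairs_pooled = res$n_pooled[i],
                          center = centers[i, ])
  })
}

storage_int <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}
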