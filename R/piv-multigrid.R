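#' Multigrid ensemble PIV over all cardiac phases
#'
#' Runs successive ensemble-correlation passes with progressively smaller
#' interrogation windows.  The default schedule starts at 48 x 48 px
#' windows with 24 px separation and refines to 16 x 16 px windows with
#' 4 px separation (7 um vector spacing at 1.75 um/px), with one
#' intermediate stage.  Each pass bilinearly interpolates the previous
#' velocity field onto the new window centers, rounds it to an integer
#' predictor shift, and correlates only the residual displacement; the
#' final vector is predictor + subpixel residual, validated by a
#' normalized-median outlier test before being used as the next predictor.
#'
#' @param stack a [frame_stack()].
#' @param alignment a `cycle_alignment` (use
#'   `cycle_alignment(Inf, n)` for steady flows).
#' @param schedule list of `c(window_size, spacing)` pairs with strictly
#'   non-increasing window sizes.
#' @param search_radius per-pass search radius in px; defaults to 12 for
#'   the first pass and 4 thereafter (recycled as needed).
#' @param mask optional lumen mask passed to [interrogation_grid()].
#' @param min_peak_corr ensemble-plane peak values below this floor are
#'   flagged invalid (uncorrelated windows, e.g. out-of-lumen or
#'   non-physical pairs).
#' @param stride frame-pairing stride.
#' @param keep_passes retain every pass's field in `$passes` (for
#'   refinement diagnostics).
#' @return a `velocity_field`: axis coordinates `x`, `y` (px), arrays
#'   `u`, `v` (ny x nx x n_bins, px/frame), `u_um_s`, `v_um_s`
#'   (exact unit conversion), `valid`, `replaced`, `peak_ratio`,
#'   `peak_corr`, plus calibration and provenance fields.
#' @export
multigrid_piv <- function(stack, alignment,
                          schedule = list(c(48L, 24L), c(32L, 12L),
                                          c(16L, 4L)),
                          search_radius = c(12L, 4L), mask = NULL,
                          min_peak_corr = 0.1, stride = 1L,
                          keep_passes = FALSE) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(alignment, "cycle_alignment"))
  if (!length(schedule)) stop("'schedule' must be non-empty")
  ws <- vapply(schedule, `[`, numeric(1), 1L)
  if (any(diff(ws) > 0))
    stop("'schedule' window sizes must be non-increasing")
  nbin <- alignment$n_phase_bins
  dims <- dim(stack$frames)[1:2]
  bin_pairs <- lapply(seq_len(nbin), pairs_in_bin,
                      alignment = alignment, stride = stride)
  if (all(vapply(bin_pairs, nrow, integer(1)) == 0))
    stop("alignment yields no frame pairs")

  field <- NULL
  passes <- list()
  for (p in seq_along(schedule)) {
    w <- as.integer(schedule[[p]][1]); sp <- as.integer(schedule[[p]][2])
    r <- as.integer(search_radius[min(p, length(search_radius))])
    grid <- interrogation_grid(dims, w, sp, search_radius = r, mask = mask)
    field <- piv_pass(stack, grid, bin_pairs, predictor_field = field,
                      min_peak_corr = min_peak_corr, pass_index = p)
    field <- validate_field(field, threshold = 2, noise_floor = 0.1)
    if (keep_passes) passes[[p]] <- field
  }
  field$passes <- if (keep_passes) passes else NULL
  field$schedule <- schedule
  field$n_pairs <- vapply(bin_pairs, nrow, integer(1))
  field
}

piv_pass <- function(stack, grid, bin_pairs, predictor_field,
                     min_peak_corr, pass_index) {
  nx <- length(grid$x); ny <- length(grid$y)
  nbin <- length(bin_pairs)
  shape <- c(ny, nx, nbin)
  u <- array(NA_real_, shape); v <- array(NA_real_, shape)
  valid <- array(FALSE, shape); ratio <- array(NA_real_, shape)
  pcorr <- array(NA_real_, shape)
  keep <- grid$keep
  centers <- grid$centers[keep, , drop = FALSE]
  kept_idx <- which(keep)                 # expand.grid order: x fastest
  grid_rc <- cbind(((kept_idx - 1L) %/% nx) + 1L,   # row  = y index
                   ((kept_idx - 1L) %% nx) + 1L)    # col  = x index
  for (b in seq_len(nbin)) {
    pairs <- bin_pairs[[b]]
    if (nrow(pairs) == 0) next
    pred <- if (is.null(predictor_field))
      matrix(0L, nrow(centers), 2L)
    else
      round(interp_field(predictor_field, centers, b))
    res <- cpp_ensemble_planes(stack$frames, dim(stack$frames),
                               as.integer(pairs[, 1]),
                               as.integer(pairs[, 2]),
                               storage_int(centers), storage_int(pred),
                               grid$window_size, grid$search_radius)
    side <- 2L * grid$search_radius + 1L
    ub <- matrix(NA_real_, ny, nx); vb <- ub; rb <- ub; cb <- ub
    ok <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(centers))) {
      if (!res$inside[i]) next
      vals <- matrix(res$planes[, i], side, side)
      if (all(vals == 0)) next
      pk <- locate_peak(vals)
      rr <- grid_rc[i, 1]; cc <- grid_rc[i, 2]
      ub[rr, cc] <- pred[i, 1] + pk$displacement[1]
      vb[rr, cc] <- pred[i, 2] + pk$displacement[2]
      rb[rr, cc] <- pk$peak_ratio
      cb[rr, cc] <- pk$peak_value
      ok[rr, cc] <- !pk$border_limited && pk$peak_value >= min_peak_corr
    }
    u[, , b] <- ub; v[, , b] <- vb
    ratio[, , b] <- rb; pcorr[, , b] <- cb; valid[, , b] <- ok
  }
  new_velocity_field(grid, u, v, valid, ratio, pcorr,
                     stack$pixel_size, stack$frame_interval, pass_index)
}

new_velocity_field <- function(grid, u, v, valid, peak_ratio, peak_corr,
                               pixel_size, frame_interval, pass_index) {
  structure(list(x = grid$x, y = grid$y, u = u, v = v,
                 u_um_s = px_frame_to_um_s(u, pixel_size, frame_interval),
                 v_um_s = px_frame_to_um_s(v, pixel_size, frame_interval),
                 valid = valid,
                 replaced = array(FALSE, dim(u)),
                 peak_ratio = peak_ratio, peak_corr = peak_corr,
                 window_size = grid$window_size, spacing = grid$spacing,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 pass_index = pass_index),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "velocity_field: %d x %d vectors x %d phase bins (window %d px, spacing %d px = %.3g um)\n",
    length(x$y), length(x$x), dim(x$u)[3], x$window_size, x$spacing,
    x$spacing * x$pixel_size))
  cat(sprintf("  valid: %.1f%%, replaced: %.1f%%\n",
              100 * mean(x$valid), 100 * mean(x$replaced)))
  invisible(x)
}

# bilinear interpolation of a field's (u, v) at pixel positions, per bin;
# unknown nodes are filled with the median measured vector so predictors
# stay finite everywhere
interp_field <- function(field, centers, bin) {
  U <- field$u[, , bin]; V <- field$v[, , bin]
  use <- (field$valid[, , bin] | field$replaced[, , bin]) & is.finite(U)
  if (!any(use)) { U[] <- 0; V[] <- 0 } else {
    U[!use] <- median(U[use]); V[!use] <- median(V[use])
  }
  cbind(bilinear(field$x, field$y, U, centers[, 1], centers[, 2]),
        bilinear(field$x, field$y, V, centers[, 1], centers[, 2]))
}

bilinear <- function(x, y, Z, qx, qy) {
  nx <- length(x); ny <- length(y)
  if (nx == 1 && ny == 1) return(rep(Z[1, 1], length(qx)))
  ix <- pmin(pmax(findInterval(qx, x), 1L), max(nx - 1L, 1L))
  iy <- pmin(pmax(findInterval(qy, y), 1L), max(ny - 1L, 1L))
  fx <- if (nx > 1) (qx - x[ix]) / (x[ix + 1] - x[ix]) else rep(0, length(qx))
  fy <- if (ny > 1) (qy - y[iy]) / (y[iy + 1] - y[iy]) else rep(0, length(qy))
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  ix2 <- pmin(ix + 1L, nx); iy2 <- pmin(iy + 1L, ny)
  Z[cbind(iy, ix)]   * (1 - fx) * (1 - fy) +
  Z[cbind(iy, ix2)]  * fx       * (1 - fy) +
  Z[cbind(iy2, ix)]  * (1 - fx) * fy       +
  Z[cbind(iy2, ix2)] * fx       * fy
}

#' Outlier detection by the normalized median test
#'
#' Applies the universal normalized-median test over each vector's
#' 8-neighborhood (residual threshold `threshold`, noise floor
#' `noise_floor` px): vectors whose normalized residual exceeds the
#' threshold are flagged invalid and replaced by the median of their valid
#' neighbors (tagged `replaced`, i.e. interpolated rather than measured).
#'
#' @param field a `velocity_field`.
#' @param threshold normalized residual threshold (default 2).
#' @param noise_floor additive noise floor in px (default 0.1).
#' @return the validated `velocity_field`.
#' @export
validate_vectors <- function(field, threshold = 2, noise_floor = 0.1) {
  stopifnot(inherits(field, "velocity_field"))
  out <- validate_field(field, threshold, noise_floor)
  if (!any(out$valid | out$replaced))
    stop("all vectors invalid after validation")
  out
}

validate_field <- function(field, threshold = 2, noise_floor = 0.1) {
  for (b in seq_len(dim(field$u)[3])) {
    U <- field$u[, , b]; V <- field$v[, , b]
    ok <- field$valid[, , b] & is.finite(U)
    if (sum(ok) < 3) next
    Um <- U; Um[!ok] <- NA; Vm <- V; Vm[!ok] <- NA
    nbU <- neighbor_stack(Um); nbV <- neighbor_stack(Vm)
    medU <- apply(nbU, 1, median, na.rm = TRUE)
    medV <- apply(nbV, 1, median, na.rm = TRUE)
    rmU <- apply(abs(nbU - medU), 1, median, na.rm = TRUE)
    rmV <- apply(abs(nbV - medV), 1, median, na.rm = TRUE)
    ru <- abs(as.vector(Um) - medU) / (rmU + noise_floor)
    rv <- abs(as.vector(Vm) - medV) / (rmV + noise_floor)
    bad <- is.finite(ru) & is.finite(rv) & sqrt(ru^2 + rv^2) > threshold
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      okv <- ok; okv[bad] <- FALSE
      Uv <- U; Uv[!okv] <- NA; Vv <- V; Vv[!okv] <- NA
      nbUv <- neighbor_stack(Uv); nbVv <- neighbor_stack(Vv)
      repU <- apply(nbUv, 1, median, na.rm = TRUE)
      repV <- apply(nbVv, 1, median, na.rm = TRUE)
      badi <- which(bad)
      has_rep <- is.finite(repU[badi]) & is.finite(repV[badi])
      U[badi[has_rep]] <- repU[badi[has_rep]]
      V[badi[has_rep]] <- repV[badi[has_rep]]
      vb <- field$valid[, , b]; rb <- field$replaced[, , b]
      vb[badi] <- FALSE
      rb[badi[has_rep]] <- TRUE
      field$valid[, , b] <- vb; field$replaced[, , b] <- rb
      field$u[, , b] <- U; field$v[, , b] <- V
      field$u_um_s[, , b] <-
        px_frame_to_um_s(U, field$pixel_size, field$frame_interval)
      field$v_um_s[, , b] <-
        px_frame_to_um_s(V, field$pixel_size, field$frame_interval)
    }
  }
  field
}

# 8-neighborhood values of every node of M, as an n x 8 matrix (NA-padded)
neighbor_stack <- function(M) {
  ny <- nrow(M); nx <- ncol(M)
  P <- matrix(NA_real_, ny + 2, nx + 2)
  P[2:(ny + 1), 2:(nx + 1)] <- M
  sh <- expand.grid(dy = -1:1, dx = -1:1)
  sh <- sh[!(sh$dy == 0 & sh$dx == 0), ]
  out <- matrix(NA_real_, ny * nx, 8)
  for (s in seq_len(8))
    out[, s] <- as.vector(P[2:(ny + 1) + sh$dy[s], 2:(nx + 1) + sh$dx[s]])
  out
}
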