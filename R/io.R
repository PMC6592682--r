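#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit TIFF pages, linearly scaled by a factor
#' recorded in the sidecar (`<name>.json`) together with the calibration,
#' the generating flow specification and seed (for synthetic stacks).
#' Ground truth, when available, is written as `<name>_truth.csv`
#' (t, x, y, u, v) on a coarse grid.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the TIFF path.
#' @export
write_sequence <- function(stack, dir, name = "stack") {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(name, ".tif"))
  mx <- max(stack$frames)
  scale <- if (mx > 0) 0.9 / mx else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) stack$frames[, , k] * scale)
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  side <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               intensity_scale = scale,
               n_frames = n_frames(stack),
               z_index = stack$z_index)
  if (!is.null(stack$flow)) {
    side$flow <- stack$flow[c("kind", "peak_speed", "mean_speed", "period",
                              "lumen", "retrograde_fraction")]
    side$seed <- stack$seed
  }
  jsonlite::write_json(side, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(stack$flow)) {
    fov <- fov_um(stack$acq)
    gx <- seq(fov[1] + 5, fov[2] - 5, length.out = 24)
    gy <- seq(fov[3] + 5, fov[4] - 5, length.out = 12)
    g <- expand.grid(x = gx, y = gy)
    tt <- seq(0, stack$flow$period, length.out = 9)[1:8]
    truth <- do.call(rbind, lapply(tt, function(t) {
      uv <- eval_flow(stack$flow, as.matrix(g), t)
      data.frame(t = t, x = g$x, y = g$y, u = uv[, 1], v = uv[, 2])
    }))
    write.csv(truth, file.path(dir, paste0(name, "_truth.csv")),
              row.names = FALSE)
  }
  invisible(tif)
}

#' Read a multi-page TIFF stack (with optional sidecar)
#'
#' @param path TIFF file; if `<stem>.json` exists beside it, calibration
#'   and the intensity scale are taken from it.
#' @param pixel_size,frame_interval calibration overrides (required when
#'   no sidecar is present).
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("stack file does not exist: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- simplify2array(pages)
  sidecar <- sub("\\.tiff?$", ".json", path)
  scale <- 1
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- side$pixel_size
    if (is.null(frame_interval)) frame_interval <- side$frame_interval
    if (!is.null(side$intensity_scale)) scale <- side$intensity_scale
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("pixel_size and frame_interval required (no sidecar found)")
  frame_stack(frames / scale, pixel_size, frame_interval)
}

#' Read and write cross-sections as JSON
#'
#' The JSON layout is a list of objects with fields `label`, `a`, `b`
#' (um), optional `dl` (um) and `flip_normal`.
#'
#' @param path JSON file.
#' @return list of [cross_section()]s.
#' @export
read_sections <- function(path) {
  if (!file.exists(path)) stop("sections file does not exist: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    cross_section(unlist(s$a), unlist(s$b),
                  dl = if (!is.null(s$dl)) s$dl else NULL,
                  label = if (!is.null(s$label)) s$label else "other",
                  flip_normal = isTRUE(s$flip_normal))
  })
}

#' @rdname read_sections
#' @param sections list of `cross_section`s.
#' @export
write_sections <- function(sections, path) {
  out <- lapply(sections, function(s)
    list(label = s$label, a = s$a, b = s$b, dl = s$dl))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a velocity field as tidy CSV
#'
#' One row per vector per phase bin, in the documented pixel frame and
#' with the exact um/s conversion.
#'
#' @param field a `velocity_field`.
#' @param path output CSV.
#' @export
write_field_csv <- function(field, path) {
  nb <- dim(field$u)[3]
  g <- expand.grid(y_px = field$y, x_px = field$x)
  rows <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(phase_bin = b, x_px = g$x_px, y_px = g$y_px,
               u_px_per_frame = as.vector(field$u[, , b]),
               v_px_per_frame = as.vector(field$v[, , b]),
               u_um_s = as.vector(field$u_um_s[, , b]),
               v_um_s = as.vector(field$v_um_s[, , b]),
               valid = as.vector(field$valid[, , b]),
               replaced = as.vector(field$replaced[, , b]),
               peak_ratio = as.vector(field$peak_ratio[, , b]))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a flow profile (and optional harmonic summary) as CSV
#'
#' @param profile a `flow_profile`.
#' @param path output CSV.
#' @param region region tag recorded in the file.
#' @export
write_profile_csv <- function(profile, path, region = "ventricle") {
  write.csv(data.frame(region = region, phase = profile$phase,
                       Q_norm_um_s = profile$Q),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param harmonic a `harmonic_result`.
#' @export
write_fhi_csv <- function(harmonic, path, region = "ventricle") {
  write.csv(data.frame(region = region, Q0 = harmonic$Q0, Q1 = harmonic$Q1,
                       FHI = harmonic$FHI),
            path, row.names = FALSE)
  invisible(path)
}
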