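#' Validate a pipeline configuration
#'
#' Checks a run configuration (a named list, or a YAML/JSON file path)
#' without running anything.  Returns a character vector of problems —
#' empty iff the configuration is runnable — each naming the offending
#' field.
#'
#' Recognized fields: `out` (output directory), `seed`, either `stack`
#' (TIFF path, with optional `pixel_size` / `frame_interval` overrides)
#' or `simulate` (list: `flow` one of control/ablated/uniform/shear/
#' poiseuille, plus optional `mean_speed`, `peak_speed`, `period`,
#' `image_shape`, `n_frames`, `density`, `noise_sigma`), `schedule`
#' (e.g. `"48:24,32:12,16:4"`), `bins` (`"auto"` or a count),
#' `search_radius`, `mask` (px bounds), `sections` (JSON path or list of
#' [cross_section()]s).
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  config <- load_config(config)
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$out) || !nzchar(config$out))
    add("out: an output directory must be given")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    add("seed: must be an integer")
  has_stack <- !is.null(config$stack)
  has_sim <- !is.null(config$simulate)
  if (!has_stack && !has_sim)
    add("stack: either a stack path or a 'simulate' block is required")
  if (has_stack && !file.exists(config$stack))
    add(sprintf("stack: file '%s' does not exist", config$stack))
  if (!is.null(config$pixel_size) &&
      (!is.numeric(config$pixel_size) || config$pixel_size <= 0))
    add("pixel_size: must be > 0")
  if (!is.null(config$frame_interval) &&
      (!is.numeric(config$frame_interval) || config$frame_interval <= 0))
    add("frame_interval: must be > 0")
  if (has_sim) {
    kinds <- c("control", "ablated", "uniform", "shear", "poiseuille")
    if (is.null(config$simulate$flow) || !config$simulate$flow %in% kinds)
      add(sprintf("simulate$flow: must be one of %s",
                  paste(kinds, collapse = ", ")))
  }
  if (!is.null(config$schedule)) {
    sched <- tryCatch(parse_schedule(config$schedule),
                      error = function(e) NULL)
    if (is.null(sched))
      add("schedule: cannot parse (expected e.g. \"48:24,32:12,16:4\")")
    else if (any(diff(vapply(sched, `[`, numeric(1), 1)) > 0))
      add("schedule: window sizes must be non-increasing")
  }
  if (!is.null(config$bins) && !identical(config$bins, "auto") &&
      (!is.numeric(config$bins) || config$bins < 1))
    add("bins: must be \"auto\" or a positive count")
  if (is.character(config$sections) && !file.exists(config$sections))
    add(sprintf("sections: file '%s' does not exist", config$sections))
  problems
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Parse a multigrid schedule string
#'
#' @param x either a list of `c(window, spacing)` pairs (returned as-is)
#'   or a string like `"48:24,32:12,16:4"`.
#' @return list of `c(window, spacing)` pairs.
#' @export
parse_schedule <- function(x) {
  if (is.list(x)) return(x)
  parts <- strsplit(strsplit(x, ",")[[1]], ":")
  lapply(parts, function(p) {
    v <- as.integer(p)
    if (length(v) != 2 || any(is.na(v)) || any(v <= 0))
      stop("bad schedule entry")
    v
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> cycle alignment -> multigrid ensemble
#' PIV -> flow profile -> FHI, writing every intermediate artifact and a
#' run manifest (config snapshot, software version, per-stage timings,
#' output checksums, collected warnings) to the output directory.  A
#' failing stage aborts with the stage name; artifacts written before the
#' failure are preserved.  Two runs with the same configuration and seed
#' produce byte-identical CSV outputs.
#'
#' @param config see [validate_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  timings <- list(); warn_log <- character(0)
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(catch_warn(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  flow <- NULL
  if (!is.null(config$simulate)) {
    stack <- stage("simulate", {
      sim <- config$simulate
      acq <- acquisition_params(
        image_shape = if (!is.null(sim$image_shape)) sim$image_shape
                      else c(128L, 512L),
        pixel_size = if (!is.null(config$pixel_size)) config$pixel_size
                     else 1.75,
        frame_interval = if (!is.null(config$frame_interval))
                           config$frame_interval else 40 / 3,
        n_frames = if (!is.null(sim$n_frames)) sim$n_frames else 500L,
        noise_sigma = if (!is.null(sim$noise_sigma)) sim$noise_sigma else 2,
        background_level = 10)
      flow <- sim_flow_field(sim, acq)
      st <- generate_sequence(flow, acq,
        density = if (!is.null(sim$density)) sim$density else 0.01,
        seed = seed)
      write_sequence(st, out, "stack")
      st
    })
  } else {
    stack <- stage("read", read_stack(config$stack,
                                      pixel_size = config$pixel_size,
                                      frame_interval = config$frame_interval))
  }

  alignment <- stage("align", {
    steady <- !is.null(flow) &&
      flow$kind %in% c("uniform", "shear", "poiseuille")
    if (steady) cycle_alignment(Inf, n_frames(stack))
    else if (identical(config$bins, "auto") || is.null(config$bins))
      align_cycles(stack)
    else align_cycles(stack, n_phase_bins = as.integer(config$bins))
  })

  field <- stage("piv", {
    sched <- if (is.null(config$schedule))
      list(c(48L, 24L), c(32L, 12L), c(16L, 4L))
    else parse_schedule(config$schedule)
    mask <- if (!is.null(config$mask)) as.numeric(config$mask)
            else if (!is.null(flow)) lumen_core_mask(flow, stack$pixel_size)
    sr <- if (!is.null(config$search_radius))
      as.integer(config$search_radius) else c(12L, 4L)
    f <- multigrid_piv(stack, alignment, schedule = sched,
                       search_radius = sr, mask = mask)
    write_field_csv(f, file.path(out, "fields.csv"))
    f
  })

  profile <- stage("flow", {
    sections <- if (is.character(config$sections))
      read_sections(config$sections)
    else if (!is.null(config$sections)) config$sections
    else default_sections(field, flow)
    write_sections(sections, file.path(out, "sections.json"))
    p <- flow_profile(field, sections)
    write_profile_csv(p, file.path(out, "profile.csv"))
    p
  })

  harmonic <- stage("fhi", {
    h <- fundamental_harmonic_index(profile)
    write_fhi_csv(h, file.path(out, "fhi.csv"))
    h
  })

  files <- c("fields.csv", "profile.csv", "fhi.csv", "sections.json")
  files <- files[file.exists(file.path(out, files))]
  manifest <- list(
    config = config[setdiff(names(config), "sections")],
    seed = seed,
    version = as.character(utils::packageVersion("cardiopiv")),
    period_frames = alignment$period,
    n_phase_bins = alignment$n_phase_bins,
    fhi = harmonic$FHI, Q0 = harmonic$Q0, Q1 = harmonic$Q1,
    timings = timings,
    checksums = as.list(tools::md5sum(file.path(out, files))),
    warnings = warn_log)
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

sim_flow_field <- function(sim, acq) {
  fov <- fov_um(acq)
  # the lumen's x extent reaches far beyond the field of view so the
  # margin band keeps feeding tracers at the inflow edge; the walls are
  # the y bounds
  lumen <- if (!is.null(sim$lumen)) as.numeric(sim$lumen)
           else c(fov[1] - 1e4, fov[2] + 1e4,
                  fov[3] + 0.15 * (fov[4] - fov[3]),
                  fov[3] + 0.85 * (fov[4] - fov[3]))
  period <- if (!is.null(sim$period)) sim$period else 0.4
  switch(sim$flow,
    control = control_flow(
      mean_speed = if (!is.null(sim$mean_speed)) sim$mean_speed else 400,
      period = period, lumen = lumen),
    ablated = ablated_flow(
      mean_speed = if (!is.null(sim$mean_speed)) sim$mean_speed else 250,
      period = period, lumen = lumen),
    flow_field(sim$flow,
      peak_speed = if (!is.null(sim$peak_speed)) sim$peak_speed else 400,
      period = period, lumen = lumen))
}

#' PIV mask covering the fast core of a channel lumen
#'
#' For parabolic-profile fields, restricts interrogation windows to the
#' band where the spatial profile exceeds `frac` of its centerline value
#' (the slow near-wall margin carries little tracer displacement and is
#' excluded, as intracardiac analyses restrict to the chamber interior).
#'
#' @param flow a [flow_field()] with a lumen.
#' @param pixel_size um/px.
#' @param frac profile fraction defining the core (default 0.35).
#' @return mask bounds `c(xmin, xmax, ymin, ymax)` in px.
#' @export
lumen_core_mask <- function(flow, pixel_size, frac = 0.35) {
  if (is.null(flow$lumen)) return(NULL)
  l <- flow$lumen
  if (flow$kind %in% c("uniform", "shear")) {
    yb <- c(l[3], l[4])
  } else {
    yc <- (l[3] + l[4]) / 2; hh <- (l[4] - l[3]) / 2
    half <- hh * sqrt(1 - frac)
    yb <- c(yc - half, yc + half)
  }
  c(l[1], l[2], yb[1], yb[2]) / pixel_size
}

# three vertical sections across the measured core band of the field
default_sections <- function(field, flow = NULL, n = 3L) {
  gx <- range(field$x) * field$pixel_size
  gy <- range(field$y) * field$pixel_size
  xs <- gx[1] + c(0.35, 0.5, 0.65)[seq_len(n)] * diff(gx)
  lapply(xs, function(x)
    cross_section(c(x, gy[1]), c(x, gy[2]),
                  pixel_size = field$pixel_size, label = "ventricle"))
}

#' Verify a run manifest against its output files
#'
#' @param path manifest JSON file.
#' @return TRUE invisibly if every checksum matches; otherwise an error
#'   naming the first mismatching file.
#' @export
verify_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  for (f in names(man$checksums)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(actual, man$checksums[[f]]))
      stop(sprintf("checksum mismatch for '%s'", f))
  }
  invisible(TRUE)
}
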