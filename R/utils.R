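#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so that seeded helpers do not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Convert velocities between px/frame and um/s
#'
#' The conversion is exact: `um_s = px_frame * pixel_size / (frame_interval
#' / 1000)`.
#'
#' @param px_frame velocity in pixels per frame.
#' @param pixel_size calibration in um/px.
#' @param frame_interval frame spacing in ms.
#' @return velocity in um/s.
#' @export
px_frame_to_um_s <- function(px_frame, pixel_size, frame_interval) {
  px_frame * pixel_size / (frame_interval / 1000)
}

#' @rdname px_frame_to_um_s
#' @param um_s velocity in um/s.
#' @export
um_s_to_px_frame <- function(um_s, pixel_size, frame_interval) {
  um_s * (frame_interval / 1000) / pixel_size
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
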