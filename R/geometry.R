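#' Screen and viewing geometry
#'
#' Describes the physical recording setup: viewing distance, physical screen
#' size and pixel resolution. These parameters drive the conversion between
#' gaze angles (degrees of visual angle) and screen pixel coordinates, and the
#' conversion of pixel distances back into the distraction angle.
#'
#' @param distance_mm Head-to-screen distance in millimetres.
#' @param width_mm,height_mm Physical screen width and height in millimetres.
#' @param width_px,height_px Screen resolution in pixels.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' geom
#' @export
screen_geometry <- function(distance_mm = 550, width_mm = 474,
                            height_mm = 297, width_px = 1680,
                            height_px = 1050) {
  vals <- c(distance_mm, width_mm, height_mm, width_px, height_px)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be strictly positive and finite")
  structure(list(distance_mm = distance_mm, width_mm = width_mm,
                 height_mm = height_mm, width_px = width_px,
                 height_px = height_px),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen geometry: %g x %g mm (%g x %g px), viewing distance %g mm\n",
              x$width_mm, x$height_mm, x$width_px, x$height_px, x$distance_mm))
  invisible(x)
}

#' Construct a gaze recording
#'
#' A monocular eye-movement recording: gaze angles in the horizontal and
#' vertical directions sampled at a fixed rate (1000 Hz by default).
#' `NA` angles mark invalid samples (blinks or tracking loss).
#'
#' @param theta_x,theta_y Gaze angles in degrees; `NA` marks invalid samples.
#' @param sample_rate Sampling rate in Hz.
#' @param timestamps Optional sample times in ms (strictly increasing).
#'   Defaults to a uniform grid starting at 0.
#' @param subject,task,round,session Recording metadata. `task` is one of
#'   `"FXS"`, `"HSS"`, `"RAN"`, `"TEX"`.
#'
#' @return An object of class `gaze_recording` with a logical `valid` mask.
#' @export
gaze_recording <- function(theta_x, theta_y, sample_rate = 1000,
                           timestamps = NULL, subject = NA_character_,
                           task = NA_character_, round = NA_integer_,
                           session = NA_integer_) {
  n <- length(theta_x)
  if (length(theta_y) != n)
    stop("theta_x and theta_y must have equal length")
  if (is.null(timestamps))
    timestamps <- (seq_len(n) - 1) * 1000 / sample_rate
  if (length(timestamps) != n)
    stop("timestamps must align with the angle sequences")
  if (n > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.na(task) && !task %in% c("FXS", "HSS", "RAN", "TEX"))
    stop("task must be one of FXS, HSS, RAN, TEX")
  structure(list(theta_x = as.numeric(theta_x),
                 theta_y = as.numeric(theta_y),
                 valid = is.finite(theta_x) & is.finite(theta_y),
                 timestamps = as.numeric(timestamps),
                 sample_rate = sample_rate,
                 subject = subject, task = task,
                 round = round, session = session),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "Gaze recording: subject %s, task %s, round %s, session %s\n  %d samples @ %g Hz (%.2f s), %.1f%% invalid\n",
    x$subject, x$task, x$round, x$session, length(x$theta_x),
    x$sample_rate, length(x$theta_x) / x$sample_rate,
    100 * mean(!x$valid)))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert gaze angles to screen pixel coordinates
#'
#' Projects gaze angles onto the screen plane using the viewing geometry:
#' `x = (l * wpix / w) * tan(theta_x) + wpix / 2` and analogously for `y`
#' (origin top-left, x rightward, y downward). Coordinates may lie off-screen;
#' they are not clipped, so off-screen gaze still contributes to distraction
#' distances.
#'
#' @param rec A [gaze_recording()].
#' @param geom A [screen_geometry()].
#'
#' @return An object of class `screen_trace`: real-valued pixel coordinates
#'   `x`, `y`, the validity mask, and (once [compute_velocity()] has been
#'   called) per-sample angular speed in deg/s.
#' @examples
#' rec <- gaze_recording(theta_x = c(0, 10), theta_y = c(0, 0))
#' angles_to_screen(rec, screen_geometry())
#' @export
angles_to_screen <- function(rec, geom) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(geom, "screen_geometry"))
  bad <- which(rec$valid & (abs(rec$theta_x) >= 90 | abs(rec$theta_y) >= 90))
  if (length(bad))
    stop(sprintf("degenerate gaze angle (|theta| >= 90 deg) at sample %d",
                 bad[1]))
  x <- (geom$distance_mm * geom$width_px / geom$width_mm) *
    tan(deg2rad(rec$theta_x)) + geom$width_px / 2
  y <- (geom$distance_mm * geom$height_px / geom$height_mm) *
    tan(deg2rad(rec$theta_y)) + geom$height_px / 2
  x[!rec$valid] <- NA_real_
  y[!rec$valid] <- NA_real_
  structure(list(x = x, y = y, valid = rec$valid,
                 velocity = NULL, sample_rate = rec$sample_rate,
                 geom = geom),
            class = "screen_trace")
}

#' Invert the screen projection back to gaze angles
#'
#' Inverse of [angles_to_screen()]; used for round-trip checks and to place
#' pixel-space stimulus targets in angle space.
#'
#' @param x,y Pixel coordinates.
#' @param geom A [screen_geometry()].
#' @return A list with `theta_x`, `theta_y` in degrees.
#' @export
screen_to_angles <- function(x, y, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  list(theta_x = rad2deg(atan((x - geom$width_px / 2) * geom$width_mm /
                                (geom$width_px * geom$distance_mm))),
       theta_y = rad2deg(atan((y - geom$height_px / 2) * geom$height_mm /
                                (geom$height_px * geom$distance_mm))))
}

#' Compute per-sample angular speed
#'
#' Backward difference of the gaze angles times the sampling rate, combined
#' across the two components as a Euclidean norm, giving deg/s. Velocity is
#' undefined (`NA`) wherever either endpoint of the difference is invalid;
#' the first sample copies the second. No smoothing is applied by default;
#' `smooth_window` enables a centred moving average.
#'
#' @param trace A `screen_trace` from [angles_to_screen()].
#' @param rec The source [gaze_recording()] (velocity is computed on angles,
#'   not pixels).
#' @param smooth_window Odd window length for an optional moving average;
#'   values < 2 disable smoothing.
#'
#' @return The trace with its `velocity` field filled in.
#' @export
compute_velocity <- function(trace, rec, smooth_window = 0) {
  stopifnot(inherits(trace, "screen_trace"), inherits(rec, "gaze_recording"))
  n <- length(rec$theta_x)
  if (sum(rec$valid) < 2)
    stop("recording too short: need at least 2 valid samples")
  v <- rep(NA_real_, n)
  if (n >= 2) {
    dx <- diff(rec$theta_x)
    dy <- diff(rec$theta_y)
    v[-1] <- sqrt(dx^2 + dy^2) * rec$sample_rate
    v[1] <- v[2]
  }
  if (smooth_window >= 2) {
    k <- as.integer(smooth_window)
    if (k %% 2 == 0) k <- k + 1L
    sm <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  trace$velocity <- v
  trace
}

#' @export
print.screen_trace <- function(x, ...) {
  cat(sprintf("Screen trace: %d samples @ %g Hz, %.1f%% invalid, velocity %s\n",
              length(x$x), x$sample_rate, 100 * mean(!x$valid),
              if (is.null(x$velocity)) "not computed" else "computed"))
  invisible(x)
}
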