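#' Mean distraction distance within a window
#'
#' Mean Euclidean pixel distance between each valid gaze sample in a window
#' and the stimulus point.
#'
#' @param x,y Gaze pixel coordinates within the window (`NA` = invalid).
#' @param target Stimulus point as `c(x, y)` in pixels.
#' @return Mean distance in pixels.
#' @examples
#' distraction_distance(c(3, 6), c(4, 8), target = c(0, 0)) # 7.5
#' @export
distraction_distance <- function(x, y, target) {
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok))
    stop("window contains no valid gaze samples")
  mean(sqrt((x[ok] - target[1])^2 + (y[ok] - target[2])^2))
}

#' Fraction of invalid (blink) samples in a window
#'
#' The per-sample average of the invalid indicator over the window. The
#' number of distinct invalid runs is also returned, since a blink *event*
#' count is the natural alternative reading of a per-window blink measure.
#'
#' @param valid Logical validity mask for the window.
#' @return A list with `fraction` (in `[0, 1]`) and `runs` (number of
#'   maximal invalid runs).
#' @export
blink_fraction <- function(valid) {
  if (!length(valid)) stop("empty window")
  r <- rle(valid)
  list(fraction = mean(!valid), runs = sum(!r$values))
}

#' Convert a pixel distraction distance to a distraction angle
#'
#' `gamma = atan(D * h / (hpix * l)) * 180 / pi`, using the physical screen
#' height, its pixel height, and the viewing distance. The distraction angle
#' is compared against the ~1 degree foveal radius to decide whether the
#' stimulus has left the zone of attentive vision.
#'
#' @param d Distraction distance in pixels (>= 0).
#' @param geom A [screen_geometry()].
#' @return Angle in degrees.
#' @export
distraction_angle <- function(d, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (any(d < 0, na.rm = TRUE)) stop("distraction distance must be >= 0")
  rad2deg(atan(d * geom$height_mm / (geom$height_px * geom$distance_mm)))
}

#' Windowed attention profile of fixation recordings
#'
#' Quantifies attention decay over the course of fixed-dot (FXS) recordings.
#' Each recording is trimmed (first `trim_head_s` seconds dropped, next
#' `keep_s` kept) and cut into non-overlapping windows of `window_s` seconds.
#' Per window the mean distraction distance D, the invalid-sample fraction P
#' and the distraction angle gamma are computed, then averaged per window
#' index across recordings. A quadratic is fitted to mean gamma versus window
#' midpoint time, and the first time at which the fitted curve reaches
#' `fovea_deg` (the foveal radius, 1 degree by default) is reported as the
#' crossing time — the recommended upper bound on recording duration.
#'
#' Windows with no valid samples are excluded from the D and gamma averages
#' but still contribute P = 1.
#'
#' @param recs A list of FXS [gaze_recording()]s.
#' @param geom A [screen_geometry()].
#' @param target Stimulus pixel position `c(x, y)`; defaults to screen
#'   centre.
#' @param window_s Window length in seconds.
#' @param trim_head_s Seconds discarded from the start of each recording.
#' @param keep_s Seconds retained after the trim.
#' @param fovea_deg Foveal radius in degrees used for the crossing time.
#'
#' @return An object of class `attention_profile`: a `windows` data frame
#'   (window index, midpoint time `t`, mean `D`, `P`, `gamma`, recordings
#'   contributing), quadratic `coefficients` (intercept, t, t^2),
#'   `crossing_time` in seconds (`NA` when the fit never reaches
#'   `fovea_deg`), and bookkeeping fields.
#' @export
attention_profile <- function(recs, geom, target = NULL, window_s = 0.5,
                              trim_head_s = 1, keep_s = 14, fovea_deg = 1) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (inherits(recs, "gaze_recording")) recs <- list(recs)
  if (is.null(target)) target <- c(geom$width_px / 2, geom$height_px / 2)
  n_win <- floor(keep_s / window_s + 1e-9)
  if (n_win < 1) stop("keep_s must cover at least one window")

  acc_D <- acc_g <- acc_P <- matrix(NA_real_, length(recs), n_win)
  used <- 0L
  for (r in seq_along(recs)) {
    rec <- recs[[r]]
    fs <- rec$sample_rate
    need <- as.integer(round((trim_head_s + keep_s) * fs))
    if (length(rec$theta_x) < need) {
      warning(sprintf("recording %d shorter than %g s; skipped",
                      r, trim_head_s + keep_s))
      next
    }
    used <- used + 1L
    trace <- angles_to_screen(rec, geom)
    off <- as.integer(round(trim_head_s * fs))
    wlen <- as.integer(round(window_s * fs))
    for (m in seq_len(n_win)) {
      idx <- (off + (m - 1L) * wlen + 1L):(off + m * wlen)
      vm <- rec$valid[idx]
      acc_P[r, m] <- mean(!vm)
      if (any(vm)) {
        D <- distraction_distance(trace$x[idx], trace$y[idx], target)
        acc_D[r, m] <- D
        acc_g[r, m] <- distraction_angle(D, geom)
      }
    }
  }
  if (used == 0L) stop("no usable recordings (all shorter than trim + keep)")

  windows <- data.frame(
    window = seq_len(n_win),
    t = trim_head_s + (seq_len(n_win) - 0.5) * window_s,
    D = colMeans(acc_D, na.rm = TRUE),
    P = colMeans(acc_P, na.rm = TRUE),
    gamma = colMeans(acc_g, na.rm = TRUE),
    n_recordings = colSums(!is.na(acc_g)))
  # time axis measured from recording onset; trimmed head included in t

  coeffs <- c(NA_real_, NA_real_, NA_real_)
  crossing <- NA_real_
  ok <- is.finite(windows$gamma)
  if (sum(ok) >= 3) {
    fit <- stats::lm(gamma ~ t + I(t^2), data = windows[ok, ])
    coeffs <- unname(stats::coef(fit))
    crossing <- .quad_crossing(coeffs, fovea_deg)
  }
  structure(list(windows = windows,
                 coefficients = c(intercept = coeffs[1], t = coeffs[2],
                                  t2 = coeffs[3]),
                 crossing_time = crossing, fovea_deg = fovea_deg,
                 window_s = window_s, trim_head_s = trim_head_s,
                 keep_s = keep_s, n_recordings = used, target = target),
            class = "attention_profile")
}

# smallest t >= 0 where c0 + c1 t + c2 t^2 >= level, NA if never;
# coefficients indistinguishable from zero are treated as zero so that flat
# profiles do not report absurd far-future crossings
.quad_crossing <- function(co, level) {
  co[abs(co) < 1e-10] <- 0
  c0 <- co[1] - level; c1 <- co[2]; c2 <- co[3]
  if (c0 >= 0) return(0)
  if (abs(c2) < 1e-15) {
    if (c1 <= 0) return(NA_real_)
    return(-c0 / c1)
  }
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) return(if (c2 > 0) NA_real_ else NA_real_)
  roots <- sort((-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2))
  roots <- roots[roots >= 0]
  if (!length(roots)) return(NA_real_)
  # polynomial is below level at t=0; first nonnegative root is the upcrossing
  for (r in roots) {
    eps <- max(1e-9, abs(r) * 1e-9)
    if (c0 + c1 * (r + eps) + c2 * (r + eps)^2 >= 0) return(r)
  }
  NA_real_
}

#' @export
print.attention_profile <- function(x, ...) {
  cat(sprintf("Attention profile over %d recording(s), %d windows of %g s\n",
              x$n_recordings, nrow(x$windows), x$window_s))
  cat(sprintf("  quadratic fit: gamma(t) = %.4g + %.4g t + %.4g t^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  if (is.na(x$crossing_time)) {
    cat(sprintf("  fitted gamma never reaches %g deg\n", x$fovea_deg))
  } else {
    cat(sprintf("  fitted gamma reaches %g deg at t = %.2f s\n",
                x$fovea_deg, x$crossing_time))
  }
  invisible(x)
}

#' @export
coef.attention_profile <- function(object, ...) object$coefficients

#' Evaluate the fitted distraction-angle curve
#'
#' @param object An [attention_profile()].
#' @param t Times (s) at which to evaluate the quadratic fit; defaults to
#'   the window midpoints.
#' @param ... Unused.
#' @return Fitted gamma values in degrees.
#' @export
predict.attention_profile <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$windows$t
  co <- object$coefficients
  unname(co[1] + co[2] * t + co[3] * t^2)
}

#' @export
plot.attention_profile <- function(x, ...) {
  w <- x$windows
  graphics::plot(w$t, w$gamma, xlab = "time (s)",
                 ylab = "distraction angle (deg)",
                 main = "Attention profile", pch = 19, ...)
  tt <- seq(min(w$t), max(w$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  graphics::abline(h = x$fovea_deg, lty = 2, col = "grey40")
  if (!is.na(x$crossing_time))
    graphics::abline(v = x$crossing_time, lty = 3, col = "firebrick")
  invisible(x)
}
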