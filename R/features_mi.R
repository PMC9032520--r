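#' Distance between two consecutive gaze points
#'
#' Euclidean pixel distance between the previous and the next gaze point —
#' the length channel of the motion-information feature.
#'
#' @param p_prev,p_next Points as `c(x, y)` in pixels.
#' @return Distance in pixels.
#' @export
step_distance <- function(p_prev, p_next) {
  sqrt(sum((p_next - p_prev)^2))
}

#' Clockwise direction of a gaze step
#'
#' Angle through which the reference vector `a = (0, 1)` must rotate
#' clockwise to align with the step vector `b = p_next - p_prev`:
#' `theta = acos(a.b / |a||b|)` when the step's x-component is >= 0, and
#' `2*pi - acos(...)` otherwise. A zero-length step returns 0.
#'
#' @param p_prev,p_next Points as `c(x, y)` in pixels.
#' @return Angle in radians, in `[0, 2*pi)`.
#' @examples
#' step_direction(c(0, 0), c(1, 1)) # pi/4
#' step_direction(c(0, 0), c(-1, 0)) # 3*pi/2
#' @export
step_direction <- function(p_prev, p_next) {
  b <- p_next - p_prev
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(0)
  ang <- acos(max(-1, min(1, b[2] / nb)))
  if (b[1] >= 0) ang else 2 * pi - ang
}

# vectorised internal form used by build_mi
.step_channels <- function(x, y) {
  dx <- diff(x)
  dy <- diff(y)
  L <- sqrt(dx^2 + dy^2)
  theta <- numeric(length(L))
  theta[is.na(L)] <- NA_real_
  nz <- !is.na(L) & L > 0
  a <- acos(pmax(-1, pmin(1, dy[nz] / L[nz])))
  theta[nz] <- ifelse(dx[nz] >= 0, a, 2 * pi - a)
  list(L = L, theta = theta)
}

#' Build the motion-information (MI) feature
#'
#' Per-step distance and clockwise direction between consecutive valid gaze
#' points, stacked as a 2 x (n-1) matrix (row 1 = distance, row 2 =
#' direction), z-scored per channel over the valid entries, and right-padded
#' with zeros to a fixed length so recordings of one dataset share a shape.
#' Steps that would span an invalid gap are dropped. A channel with zero
#' variance z-scores to all zeros.
#'
#' @param trace A `screen_trace` (see [angles_to_screen()]).
#' @param target_len Nominal number of samples of the segment; the feature
#'   matrix has `target_len - 1` columns. Defaults to the trace length.
#' @param events Optional event table from [classify_ivt()]; when supplied
#'   together with `fixation_only = TRUE`, only steps internal to fixation
#'   segments are used.
#' @param fixation_only Restrict steps to fixation segments.
#'
#' @return An object of class `mi_feature`: `channels` (2 x (target_len-1)
#'   matrix), `valid_length` (number of real steps) and `target_len`.
#' @export
build_mi <- function(trace, target_len = NULL, events = NULL,
                     fixation_only = FALSE) {
  stopifnot(inherits(trace, "screen_trace"))
  n <- length(trace$x)
  if (is.null(target_len)) target_len <- n
  if (target_len < 2) stop("target_len must be at least 2")
  keep <- trace$valid[-n] & trace$valid[-1]
  if (fixation_only) {
    if (is.null(events)) stop("fixation_only requires an event table")
    infix <- rep(FALSE, n)
    fx <- events[events$kind == "fixation", , drop = FALSE]
    for (i in seq_len(nrow(fx)))
      infix[fx$start[i]:(fx$end[i] - 1L)] <- TRUE
    keep <- keep & infix[-n] & infix[-1]
  }
  if (sum(trace$valid) < 2 || !any(keep))
    stop("need at least 2 consecutive valid samples to build MI")
  ch <- .step_channels(trace$x, trace$y)
  L <- ch$L[keep]
  theta <- ch$theta[keep]
  m <- length(L)
  if (m > target_len - 1) stop("trace longer than target_len")
  channels <- matrix(0, 2, target_len - 1)
  channels[1, seq_len(m)] <- .zscore(L)
  channels[2, seq_len(m)] <- .zscore(theta)
  structure(list(channels = channels, valid_length = m,
                 target_len = target_len),
            class = "mi_feature")
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.mi_feature <- function(x, ...) {
  cat(sprintf("MI feature: 2 x %d (valid steps: %d)\n",
              ncol(x$channels), x$valid_length))
  invisible(x)
}
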