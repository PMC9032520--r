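#' Decide whether a saccade trajectory is long enough to keep
#'
#' A saccade's spatial extent is its maximum horizontal span (max x - min x)
#' and maximum vertical span. Trajectories that are "too short" are
#' discarded before rasterization. Under the default `mode = "both"` a
#' trajectory is dropped only when *neither* direction reaches
#' `min_extent_px`; `mode = "either"` drops it as soon as one direction
#' falls short.
#'
#' @param x,y Pixel coordinates of the saccade samples (`NA` allowed).
#' @param min_extent_px Extent threshold in pixels.
#' @param mode `"both"` (drop when both spans are below threshold) or
#'   `"either"` (drop when either is).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_saccade <- function(x, y, min_extent_px = 10, mode = c("both", "either")) {
  mode <- match.arg(mode)
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) return(FALSE)
  w <- diff(range(x[ok]))
  h <- diff(range(y[ok]))
  if (mode == "both") w >= min_extent_px || h >= min_extent_px
  else w >= min_extent_px && h >= min_extent_px
}

#' Rasterize saccade trajectories onto a pixel canvas
#'
#' Every valid sample of every kept saccade increments its nearest-pixel
#' cell; all kept saccades of a recording accumulate onto one canvas.
#' Off-canvas samples are clipped to the border cell. No line interpolation
#' is performed: at 1000 Hz consecutive saccade samples are dense enough to
#' trace the path.
#'
#' @param events Event table from [classify_ivt()] (only `saccade` rows are
#'   used).
#' @param trace The `screen_trace` the events index into.
#' @param canvas Canvas size `c(width_px, height_px)`.
#' @param min_extent_px,mode Passed to [filter_saccade()].
#'
#' @return A list: `counts` (matrix with `canvas[2]` rows and `canvas[1]`
#'   columns; rows index y, columns x) and `n_saccades_used`.
#' @export
rasterize_saccades <- function(events, trace, canvas = c(1680, 1050),
                               min_extent_px = 10, mode = "both") {
  stopifnot(inherits(trace, "screen_trace"))
  counts <- matrix(0, canvas[2], canvas[1])
  sacc <- events[events$kind == "saccade", , drop = FALSE]
  used <- 0L
  for (i in seq_len(nrow(sacc))) {
    idx <- sacc$start[i]:(sacc$end[i] - 1L)
    sx <- trace$x[idx]
    sy <- trace$y[idx]
    if (!filter_saccade(sx, sy, min_extent_px, mode)) next
    used <- used + 1L
    ok <- is.finite(sx) & is.finite(sy)
    px <- pmin(pmax(round(sx[ok]), 0), canvas[1] - 1) + 1
    py <- pmin(pmax(round(sy[ok]), 0), canvas[2] - 1) + 1
    for (j in seq_along(px))
      counts[py[j], px[j]] <- counts[py[j], px[j]] + 1
  }
  list(counts = counts, n_saccades_used = used)
}

# overlap-weight matrix mapping n_in cells onto n_out cells; each row of the
# input contributes its full mass exactly once (columns sum to 1)
.area_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  scale <- n_out / n_in
  for (r in seq_len(n_in)) {
    a <- (r - 1) * scale
    b <- r * scale
    lo <- floor(a) + 1
    hi <- ceiling(b)
    for (i in lo:min(hi, n_out)) {
      ov <- min(b, i) - max(a, i - 1)
      if (ov > 0) W[i, r] <- ov / scale
    }
  }
  W
}

#' Finalize a saccade distribution map
#'
#' Downscales the full-resolution count canvas to `size x size` by exact
#' area-weighted resampling (mass preserving) and normalizes it to sum to 1,
#' yielding a probability image of where saccade samples fall on the screen.
#' A zero-count canvas yields an all-zero map.
#'
#' @param counts Count matrix from [rasterize_saccades()] (rows = y).
#' @param size Output grid side length.
#' @param n_saccades_used Bookkeeping count carried into the result.
#'
#' @return An object of class `sdm`: `grid` (`size` x `size`, nonnegative,
#'   summing to 1 unless empty), `n_saccades_used`, `canvas`.
#' @export
finalize_sdm <- function(counts, size = 128, n_saccades_used = NA_integer_) {
  if (any(counts < 0)) stop("count grid must be nonnegative")
  A <- .area_weights(size, nrow(counts))
  B <- .area_weights(size, ncol(counts))
  grid <- A %*% counts %*% t(B)
  tot <- sum(grid)
  if (tot > 0) grid <- grid / tot
  else n_saccades_used <- 0L
  structure(list(grid = grid, n_saccades_used = n_saccades_used,
                 canvas = c(ncol(counts), nrow(counts))),
            class = "sdm")
}

#' Build the saccade distribution map of a recording
#'
#' Convenience wrapper: filter + rasterize + downscale + normalize.
#'
#' @inheritParams rasterize_saccades
#' @param size Output grid side length.
#' @return An `sdm` object (see [finalize_sdm()]).
#' @export
build_sdm <- function(events, trace, canvas = c(1680, 1050), size = 128,
                      min_extent_px = 10, mode = "both") {
  r <- rasterize_saccades(events, trace, canvas, min_extent_px, mode)
  finalize_sdm(r$counts, size, r$n_saccades_used)
}

#' @export
print.sdm <- function(x, ...) {
  cat(sprintf("SDM: %d x %d probability grid from %s saccade(s), canvas %d x %d\n",
              nrow(x$grid), ncol(x$grid), x$n_saccades_used,
              x$canvas[1], x$canvas[2]))
  invisible(x)
}

#' @export
plot.sdm <- function(x, ...) {
  graphics::image(t(x$grid)[, nrow(x$grid):1], col = grey.colors(64, 1, 0),
                  axes = FALSE, main = "Saccade distribution map", ...)
  invisible(x)
}
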