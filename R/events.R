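#' Classify samples into fixations and saccades (I-VT)
#'
#' Velocity-threshold identification. Samples slower than `fix_thresh` are
#' fixation; contiguous runs at or above it are saccade candidates, confirmed
#' as saccades only when their peak velocity reaches `sac_peak_thresh`
#' (unconfirmed candidates are folded back into the surrounding fixation).
#' Runs of invalid samples become `invalid` segments. Saccades shorter than
#' `min_sac_ms` are relabelled fixation; fixations shorter than `min_fix_ms`
#' are absorbed into the longer adjacent non-invalid segment. The returned
#' segments tile the recording exactly.
#'
#' Samples whose velocity is undefined but which are themselves valid (the
#' first sample of a valid run, where the backward difference spans a gap)
#' inherit the next defined velocity in their run.
#'
#' @param trace A `screen_trace` with velocity computed
#'   (see [compute_velocity()]).
#' @param fix_thresh Fixation velocity threshold in deg/s.
#' @param sac_peak_thresh Peak velocity a candidate run must reach to be
#'   confirmed as a saccade, deg/s.
#' @param min_fix_ms,min_sac_ms Minimum event durations in ms.
#'
#' @return A data frame of event segments with columns `kind` (one of
#'   `"fixation"`, `"saccade"`, `"invalid"`), half-open sample range
#'   `start`/`end` (1-based start, exclusive end) and `duration_ms`.
#' @examples
#' rec <- gaze_recording(theta_x = rep(0, 200), theta_y = rep(0, 200))
#' tr <- compute_velocity(angles_to_screen(rec, screen_geometry()), rec)
#' classify_ivt(tr)
#' @export
classify_ivt <- function(trace, fix_thresh = 100, sac_peak_thresh = 300,
                         min_fix_ms = 50, min_sac_ms = 10) {
  stopifnot(inherits(trace, "screen_trace"))
  if (is.null(trace$velocity))
    stop("trace has no velocity; call compute_velocity() first")
  if (fix_thresh >= sac_peak_thresh)
    stop("fix_thresh must be below sac_peak_thresh")
  n <- length(trace$x)
  valid <- trace$valid
  if (!any(valid))
    stop("recording contains no valid samples; no events to classify")
  ms_per_sample <- 1000 / trace$sample_rate

  # fill undefined velocities within each valid run (leading-edge convention)
  v <- trace$velocity
  run <- rle(valid)
  pos <- 1L
  for (i in seq_along(run$lengths)) {
    len <- run$lengths[i]
    if (run$values[i]) {
      idx <- pos:(pos + len - 1L)
      vv <- v[idx]
      if (anyNA(vv)) {
        def <- which(!is.na(vv))
        vv[is.na(vv)] <- if (length(def)) vv[def[1]] else 0
        v[idx] <- vv
      }
    }
    pos <- pos + len
  }

  lab <- ifelse(!valid, "invalid",
                ifelse(v >= fix_thresh, "candidate", "fixation"))
  segs <- .runs(lab)

  # confirm saccade candidates by peak velocity
  for (i in seq_len(nrow(segs))) {
    if (segs$kind[i] == "candidate") {
      peak <- max(v[segs$start[i]:(segs$end[i] - 1L)], na.rm = TRUE)
      segs$kind[i] <- if (peak >= sac_peak_thresh) "saccade" else "fixation"
    }
  }
  segs <- .merge_adjacent(segs)

  # minimum-duration hygiene
  dur <- (segs$end - segs$start) * ms_per_sample
  segs$kind[segs$kind == "saccade" & dur < min_sac_ms] <- "fixation"
  segs <- .merge_adjacent(segs)
  dur <- (segs$end - segs$start) * ms_per_sample
  short_fix <- which(segs$kind == "fixation" & dur < min_fix_ms)
  for (i in short_fix) {
    nb <- c(if (i > 1) i - 1L, if (i < nrow(segs)) i + 1L)
    nb <- nb[segs$kind[nb] == "saccade"]
    if (length(nb)) {
      lens <- segs$end[nb] - segs$start[nb]
      segs$kind[i] <- segs$kind[nb[which.max(lens)]]
    }
  }
  segs <- .merge_adjacent(segs)
  segs$duration_ms <- (segs$end - segs$start) * ms_per_sample
  rownames(segs) <- NULL
  segs
}

.runs <- function(lab) {
  r <- rle(lab)
  end <- cumsum(r$lengths)
  data.frame(kind = r$values,
             start = c(1L, utils::head(end, -1) + 1L),
             end = end + 1L,  # half-open
             stringsAsFactors = FALSE)
}

.merge_adjacent <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  keep <- c(TRUE, segs$kind[-1] != segs$kind[-nrow(segs)])
  grp <- cumsum(keep)
  data.frame(kind = segs$kind[keep],
             start = tapply(segs$start, grp, min),
             end = tapply(segs$end, grp, max),
             stringsAsFactors = FALSE)
}

#' Extract blink (invalid-sample) runs
#'
#' Blinks are stored as runs of invalid (`NaN`) samples in the recording.
#' Every maximal invalid run is reported once; runs shorter than
#' `min_blink_ms` are still reported but flagged as short.
#'
#' @param rec A [gaze_recording()].
#' @param min_blink_ms Duration below which a run is flagged short
#'   (default 0: nothing is flagged).
#'
#' @return A data frame with half-open sample range `start`/`end`,
#'   `duration_ms` and a logical `short` flag; zero rows when the recording
#'   has no invalid samples.
#' @export
extract_blinks <- function(rec, min_blink_ms = 0) {
  stopifnot(inherits(rec, "gaze_recording"))
  ms_per_sample <- 1000 / rec$sample_rate
  if (all(rec$valid))
    return(data.frame(start = integer(), end = integer(),
                      duration_ms = numeric(), short = logical()))
  segs <- .runs(ifelse(rec$valid, "v", "i"))
  segs <- segs[segs$kind == "i", , drop = FALSE]
  out <- data.frame(start = segs$start, end = segs$end,
                    duration_ms = (segs$end - segs$start) * ms_per_sample)
  out$short <- out$duration_ms < min_blink_ms
  rownames(out) <- NULL
  out
}

#' Preprocess a recording end to end
#'
#' Convenience wrapper: screen projection, velocity, I-VT event segmentation
#' and blink extraction in one call.
#'
#' @param rec A [gaze_recording()].
#' @param geom A [screen_geometry()].
#' @param ... Passed to [classify_ivt()].
#' @return A list with elements `trace`, `events`, `blinks`.
#' @export
preprocess_recording <- function(rec, geom, ...) {
  trace <- compute_velocity(angles_to_screen(rec, geom), rec)
  list(trace = trace,
       events = classify_ivt(trace, ...),
       blinks = extract_blinks(rec))
}
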