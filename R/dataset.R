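#' Build a feature dataset from segmented recordings
#'
#' Reads each recording, cuts it into segments, preprocesses every segment
#' independently (screen projection, velocity, I-VT events) and extracts the
#' requested features: MI channel matrices (optionally on a decimated trace;
#' the protocol leaves the network input rate open, so desk-scale runs typically
#' decimate 1000 Hz traces before MI extraction) and/or saccade distribution
#' maps.
#'
#' @param recordings Data frame of recordings (`read_manifest(dir)$recordings`)
#'   or a cohort directory path.
#' @param segment_s Segment duration, seconds.
#' @param usable_s Seconds of each recording used (see
#'   [segment_recordings()]).
#' @param features Character vector from `c("mi", "sdm")`.
#' @param geom A [screen_geometry()].
#' @param downsample Integer decimation factor applied to the trace before
#'   MI extraction (1 = full rate).
#' @param sdm_size SDM grid side length.
#' @param min_extent_px Saccade extent filter threshold (see
#'   [filter_saccade()]).
#' @param ... Passed to [classify_ivt()].
#'
#' @return A list with `mi` (array `(2, len, n)` or `NULL`), `sdm` (array
#'   `(1, sdm_size^2, n)` or `NULL`), `labels` (subject per segment) and
#'   `segments` (the segment table).
#' @export
build_feature_dataset <- function(recordings, segment_s = 5, usable_s = NULL,
                                  features = "mi", geom = screen_geometry(),
                                  downsample = 1, sdm_size = 128,
                                  min_extent_px = 10, ...) {
  if (is.character(recordings) && length(recordings) == 1)
    recordings <- read_manifest(recordings)$recordings
  if (is.null(usable_s)) usable_s <- min(recordings$duration_s)
  segs <- segment_recordings(recordings, segment_s, usable_s)
  use_mi <- "mi" %in% features
  use_sdm <- "sdm" %in% features
  n <- nrow(segs)

  mi_len <- NULL
  mi_arr <- sdm_arr <- NULL
  cache_path <- ""
  rec <- NULL
  for (i in seq_len(n)) {
    if (segs$path[i] != cache_path) {
      rec <- read_recording(segs$path[i])
      cache_path <- segs$path[i]
    }
    fs <- rec$sample_rate
    idx <- (segs$start_s[i] * fs + 1):((segs$start_s[i] + segs$segment_s[i]) * fs)
    sub <- gaze_recording(rec$theta_x[idx], rec$theta_y[idx],
                          sample_rate = fs, subject = rec$subject,
                          task = rec$task, round = rec$round,
                          session = rec$session)
    if (use_mi) {
      dec <- seq(1, length(idx), by = downsample)
      sub_dec <- gaze_recording(sub$theta_x[dec], sub$theta_y[dec],
                                sample_rate = fs / downsample)
      tr <- angles_to_screen(sub_dec, geom)
      if (is.null(mi_len)) {
        mi_len <- length(dec) - 1L
        mi_arr <- array(0, c(2, mi_len, n))
      }
      mi_arr[, , i] <- build_mi(tr, target_len = length(dec))$channels
    }
    if (use_sdm) {
      pp <- preprocess_recording(sub, geom, ...)
      sdm <- build_sdm(pp$events, pp$trace,
                       canvas = c(geom$width_px, geom$height_px),
                       size = sdm_size, min_extent_px = min_extent_px)
      if (is.null(sdm_arr)) sdm_arr <- array(0, c(1, sdm_size^2, n))
      sdm_arr[1, , i] <- as.numeric(sdm$grid)
    }
  }
  list(mi = mi_arr, sdm = sdm_arr, labels = segs$subject, segments = segs)
}
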