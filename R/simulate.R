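#' Per-subject oculomotor signature parameters
#'
#' The simulator injects identity through a handful of oculomotor traits:
#' fixation tremor amplitude, main-sequence peak-velocity scaling, saccade
#' curvature, stimulus-to-saccade latency, slow fixation drift, and blink
#' statistics. Tremor is modelled as an Ornstein-Uhlenbeck process with a
#' 50 ms time constant so fixation sample velocities stay far below the
#' 100 deg/s fixation threshold at physiological amplitudes.
#'
#' @param tremor_sd Fixation noise amplitude, degrees (typical 0.02-0.2).
#' @param drift_rate Slow fixation drift scale, deg per sqrt(s).
#' @param saccade_vpeak_scale Multiplier on the main-sequence peak velocity.
#' @param saccade_curvature Lateral deviation of saccade paths, as a
#'   fraction of amplitude.
#' @param blink_rate Blink events per minute.
#' @param blink_dur_ms Mean blink duration, ms.
#' @param latency_ms Stimulus-to-saccade latency, ms.
#' @param seed Subject-level seed.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(tremor_sd = 0.05, drift_rate = 0.02,
                           saccade_vpeak_scale = 1, saccade_curvature = 0.08,
                           blink_rate = 10, blink_dur_ms = 150,
                           latency_ms = 180, seed = 1) {
  vals <- c(tremor_sd, drift_rate, saccade_vpeak_scale, saccade_curvature,
            blink_rate, blink_dur_ms, latency_ms)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all oculomotor parameters must be nonnegative and finite")
  structure(list(tremor_sd = tremor_sd, drift_rate = drift_rate,
                 saccade_vpeak_scale = saccade_vpeak_scale,
                 saccade_curvature = saccade_curvature,
                 blink_rate = blink_rate, blink_dur_ms = blink_dur_ms,
                 latency_ms = latency_ms, seed = seed),
            class = "subject_params")
}

#' Draw a cohort of subject parameter sets
#'
#' Subject traits are drawn from log-normal hyper-distributions centred on
#' the [subject_params()] defaults. `spread` widens the hyper-distributions;
#' values around 2 give clearly separated oculomotor signatures, values
#' near 0 make subjects nearly identical.
#'
#' @param n Number of subjects.
#' @param master_seed Seed for the draw.
#' @param spread Multiplier on the hyper-distribution widths.
#' @return A list of `subject_params`.
#' @export
draw_subject_params <- function(n, master_seed = 1, spread = 1) {
  set.seed(master_seed)
  lapply(seq_len(n), function(i) {
    subject_params(
      tremor_sd = stats::rlnorm(1, log(0.05), 0.35 * spread),
      drift_rate = stats::rlnorm(1, log(0.02), 0.3 * spread),
      saccade_vpeak_scale = stats::rlnorm(1, log(1), 0.2 * spread),
      saccade_curvature = stats::rlnorm(1, log(0.08), 0.35 * spread),
      blink_rate = stats::rlnorm(1, log(10), 0.25 * spread),
      blink_dur_ms = max(60, stats::rnorm(1, 150, 15 * spread)),
      latency_ms = max(80, stats::rnorm(1, 180, 20 * spread)),
      seed = master_seed + i)
  })
}

#' Stimulus script for a recording task
#'
#' Generates the target sequence a task presents on screen: `FXS` one
#' centred dot for the whole recording; `HSS` alternation between two
#' horizontally separated points at a fixed cadence; `RAN` uniform random
#' on-screen jumps; `TEX` a reading-like left-to-right, top-to-bottom sweep
#' with occasional regressions.
#'
#' @param task One of `"FXS"`, `"HSS"`, `"RAN"`, `"TEX"`.
#' @param duration_s Recording duration in seconds.
#' @param geom A [screen_geometry()].
#' @param seed Seed (used by the random tasks).
#' @param cadence_s Target change period for HSS/RAN (TEX uses a quarter of
#'   it per word step).
#' @return An object of class `stimulus_script`: a data frame with target
#'   pixel positions `x`, `y`, `onset_s` and `duration_s`, with the task in
#'   attribute `task`.
#' @export
make_stimulus <- function(task = c("FXS", "HSS", "RAN", "TEX"), duration_s,
                          geom = screen_geometry(), seed = 1,
                          cadence_s = 1) {
  task <- match.arg(task)
  if (duration_s <= 0) stop("duration_s must be positive")
  cx <- geom$width_px / 2
  cy <- geom$height_px / 2
  set.seed(seed)
  if (task == "FXS") {
    df <- data.frame(x = cx, y = cy, onset_s = 0, duration_s = duration_s)
  } else if (task == "HSS") {
    n <- ceiling(duration_s / cadence_s)
    xs <- rep(c(cx - 0.3 * geom$width_px, cx + 0.3 * geom$width_px),
              length.out = n)
    df <- data.frame(x = xs, y = cy, onset_s = (seq_len(n) - 1) * cadence_s,
                     duration_s = pmin(cadence_s,
                                       duration_s - (seq_len(n) - 1) * cadence_s))
  } else if (task == "RAN") {
    n <- ceiling(duration_s / cadence_s)
    df <- data.frame(x = stats::runif(n, 0.1, 0.9) * geom$width_px,
                     y = stats::runif(n, 0.1, 0.9) * geom$height_px,
                     onset_s = (seq_len(n) - 1) * cadence_s,
                     duration_s = pmin(cadence_s,
                                       duration_s - (seq_len(n) - 1) * cadence_s))
  } else {
    step_s <- cadence_s / 4
    n <- ceiling(duration_s / step_s)
    ncol_ <- 12
    col <- 0
    row <- 0
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      xs[i] <- (0.1 + 0.8 * col / (ncol_ - 1)) * geom$width_px
      ys[i] <- (0.15 + 0.12 * row) * geom$height_px
      if (stats::runif(1) < 0.08 && col >= 2) col <- col - 2
      else col <- col + 1
      if (col >= ncol_) { col <- 0; row <- (row + 1) %% 6 }
    }
    df <- data.frame(x = xs, y = ys, onset_s = (seq_len(n) - 1) * step_s,
                     duration_s = pmin(step_s,
                                       duration_s - (seq_len(n) - 1) * step_s))
  }
  df <- df[df$duration_s > 0, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, task = task, class = c("stimulus_script", "data.frame"))
}

# main-sequence peak velocity (deg/s); saturating in amplitude, floored at
# 320 deg/s for amplitudes >= 2 deg so I-VT (300 deg/s peak) always detects
# the saccade
.main_sequence_vpeak <- function(amp, scale) {
  vp <- scale * 600 * (1 - exp(-amp / 8))
  ifelse(amp >= 2, pmax(vp, 320), vp)
}

#' Simulate one gaze recording
#'
#' Renders a stimulus script into a 1000 Hz gaze-angle trace with the
#' subject's oculomotor signature: fixations are the target position plus
#' Ornstein-Uhlenbeck tremor and slow drift; saccades follow minimum-jerk
#' position profiles whose peak velocity obeys a main-sequence law (floored
#' at 320 deg/s for amplitudes of 2 degrees and above, guaranteeing
#' velocity-threshold detectability); blinks are Poisson-distributed runs of
#' invalid samples. An optional attention-drift law makes the expected
#' distraction angle of an FXS recording follow a prescribed curve
#' `gamma(t)`.
#'
#' @param script A [make_stimulus()] script.
#' @param params A [subject_params()].
#' @param geom A [screen_geometry()].
#' @param sample_rate Hz.
#' @param attention_drift Optional function `gamma(t_seconds) -> degrees`
#'   giving the deterministic radial offset of gaze from the target; its
#'   direction wanders slowly per recording.
#' @param seed Recording-level seed (defaults to the subject seed).
#' @param subject,round,session Metadata stamped on the recording.
#' @return A [gaze_recording()].
#' @export
simulate_recording <- function(script, params, geom = screen_geometry(),
                               sample_rate = 1000, attention_drift = NULL,
                               seed = NULL, subject = NA_character_,
                               round = NA_integer_, session = NA_integer_) {
  stopifnot(inherits(script, "stimulus_script"),
            inherits(params, "subject_params"))
  if (is.null(seed)) seed <- params$seed
  set.seed(seed)
  duration_s <- max(script$onset_s + script$duration_s)
  n <- as.integer(round(duration_s * sample_rate))
  tt <- (seq_len(n) - 1) / sample_rate

  ang <- lapply(seq_len(nrow(script)),
                function(i) screen_to_angles(script$x[i], script$y[i], geom))
  tx_t <- vapply(ang, `[[`, numeric(1), "theta_x")
  ty_t <- vapply(ang, `[[`, numeric(1), "theta_y")

  # piecewise trajectory: hold position, then minimum-jerk saccade to the
  # next target after the subject's latency
  theta_x <- numeric(n)
  theta_y <- numeric(n)
  cur <- c(tx_t[1], ty_t[1])
  filled <- 0L
  put <- function(upto, fx, fy) {
    if (upto > filled) {
      idx <- (filled + 1L):upto
      theta_x[idx] <<- fx(idx)
      theta_y[idx] <<- fy(idx)
      filled <<- upto
    }
  }
  for (i in seq_len(nrow(script))[-1]) {
    onset <- script$onset_s[i] + params$latency_ms / 1000
    i0 <- min(n, as.integer(round(onset * sample_rate)))
    put(i0, function(idx) rep(cur[1], length(idx)),
        function(idx) rep(cur[2], length(idx)))
    tgt <- c(tx_t[i], ty_t[i])
    amp <- sqrt(sum((tgt - cur)^2))
    if (amp > 1e-6) {
      vp <- .main_sequence_vpeak(amp, params$saccade_vpeak_scale)
      dur_s <- 1.875 * amp / vp
      m <- max(2L, as.integer(round(dur_s * sample_rate)))
      i1 <- min(n, i0 + m)
      if (i1 > i0) {
        u <- (seq_len(i1 - i0)) / m
        s <- 10 * u^3 - 15 * u^4 + 6 * u^5
        lat <- params$saccade_curvature * amp * sin(pi * u)
        dirv <- (tgt - cur) / amp
        perp <- c(-dirv[2], dirv[1])
        seg_x <- cur[1] + s * (tgt[1] - cur[1]) + lat * perp[1]
        seg_y <- cur[2] + s * (tgt[2] - cur[2]) + lat * perp[2]
        idx0 <- i0
        put(i1, function(idx) seg_x[idx - idx0],
            function(idx) seg_y[idx - idx0])
      }
      cur <- tgt
    }
  }
  put(n, function(idx) rep(cur[1], length(idx)),
      function(idx) rep(cur[2], length(idx)))

  # Ornstein-Uhlenbeck tremor, tau = 50 ms, stationary sd = tremor_sd
  rho <- exp(-1 / (0.05 * sample_rate))
  innov <- params$tremor_sd * sqrt(1 - rho^2)
  trem_x <- stats::filter(stats::rnorm(n, 0, innov), rho, "recursive")
  trem_y <- stats::filter(stats::rnorm(n, 0, innov), rho, "recursive")
  theta_x <- theta_x + as.numeric(trem_x)
  theta_y <- theta_y + as.numeric(trem_y)

  if (!is.null(attention_drift)) {
    # deterministic radial offset with a slowly wandering direction
    phi <- cumsum(stats::rnorm(n, 0, 0.5 / sqrt(sample_rate))) +
      stats::runif(1, 0, 2 * pi)
    r <- attention_drift(tt)
    theta_x <- theta_x + r * cos(phi)
    theta_y <- theta_y + r * sin(phi)
  } else if (params$drift_rate > 0) {
    step_sd <- params$drift_rate / sqrt(sample_rate)
    theta_x <- theta_x + cumsum(stats::rnorm(n, 0, step_sd))
    theta_y <- theta_y + cumsum(stats::rnorm(n, 0, step_sd))
  }

  # blinks: Poisson events, truncated-normal durations
  n_blinks <- stats::rpois(1, params$blink_rate * duration_s / 60)
  if (n_blinks > 0) {
    starts <- sort(stats::runif(n_blinks, 0, duration_s))
    for (b in seq_len(n_blinks)) {
      dur <- max(30, stats::rnorm(1, params$blink_dur_ms,
                                  0.2 * params$blink_dur_ms)) / 1000
      i0 <- max(1L, as.integer(round(starts[b] * sample_rate)))
      i1 <- min(n, i0 + as.integer(round(dur * sample_rate)))
      theta_x[i0:i1] <- NA_real_
      theta_y[i0:i1] <- NA_real_
    }
  }

  gaze_recording(theta_x, theta_y, sample_rate = sample_rate,
                 subject = subject, task = attr(script, "task"),
                 round = round, session = session)
}

#' Simulate a cohort and write it to disk
#'
#' Draws per-subject oculomotor parameters, simulates
#' `rounds x sessions x tasks` recordings per subject, writes each to a CSV
#' in the package's recording schema, and writes a manifest JSON capturing
#' every parameter for provenance. All randomness derives from
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param out_dir Output directory (created if needed).
#' @param tasks Character vector of tasks.
#' @param rounds,sessions Recording structure per subject.
#' @param recording_s Duration of each recording, seconds.
#' @param geom A [screen_geometry()].
#' @param master_seed Master seed.
#' @param spread Hyper-distribution spread (see [draw_subject_params()]).
#' @param cadence_s Stimulus cadence (see [make_stimulus()]).
#' @param sample_rate Hz.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
simulate_cohort <- function(n_subjects, out_dir, tasks = "HSS", rounds = 8,
                            sessions = 2, recording_s = 60,
                            geom = screen_geometry(), master_seed = 1,
                            spread = 1, cadence_s = 1, sample_rate = 1000) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subj_par <- draw_subject_params(n_subjects, master_seed, spread)
  recs <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    for (r in seq_len(rounds)) for (ses in seq_len(sessions))
      for (tk in tasks) {
        k <- k + 1L
        rec_seed <- (master_seed + 1009 * k) %% .Machine$integer.max
        script <- make_stimulus(tk, recording_s, geom, seed = rec_seed,
                                cadence_s = cadence_s)
        rec <- simulate_recording(script, subj_par[[s]], geom,
                                  sample_rate = sample_rate, seed = rec_seed,
                                  subject = sid, round = r, session = ses)
        path <- file.path(out_dir,
                          sprintf("%s_R%d_S%d_%s.csv", sid, r, ses, tk))
        write_recording(rec, path)
        recs[[k]] <- list(path = basename(path), subject = sid, task = tk,
                          round = r, session = ses,
                          duration_s = recording_s, seed = rec_seed)
      }
  }
  manifest <- list(
    n_subjects = n_subjects, tasks = as.list(tasks), rounds = rounds,
    sessions = sessions, recording_s = recording_s,
    sample_rate = sample_rate, master_seed = master_seed, spread = spread,
    cadence_s = cadence_s,
    geometry = unclass(geom),
    subjects = lapply(seq_len(n_subjects), function(s)
      c(list(id = sprintf("S%03d", s)), unclass(subj_par[[s]]))),
    recordings = recs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
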