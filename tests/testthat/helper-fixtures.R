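# Shared fixtures built in code: a small geometry, quick recording builders.

test_geom <- function() screen_geometry()

# recording whose velocity profile is fully specified: theta_x advances by
# `step_deg` per sample inside [from, to), constant elsewhere
ramp_recording <- function(n, from, to, step_deg, sample_rate = 1000) {
  dx <- numeric(n)
  if (to > from) dx[(from + 1):to] <- step_deg
  gaze_recording(cumsum(dx), numeric(n), sample_rate = sample_rate)
}

velocity_trace <- function(rec, geom = test_geom()) {
  compute_velocity(angles_to_screen(rec, geom), rec)
}

# a screen_trace built directly from pixel coordinates (no projection),
# for feature-level tests that live purely in pixel space
pixel_trace <- function(x, y, sample_rate = 1000, velocity = NULL) {
  structure(list(x = x, y = y, valid = is.finite(x) & is.finite(y),
                 velocity = velocity, sample_rate = sample_rate,
                 geom = NULL),
            class = "screen_trace")
}

# event table wrapping the whole index range as one saccade
one_saccade_events <- function(n) {
  data.frame(kind = "saccade", start = 1L, end = n + 1L,
             duration_ms = n)
}
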