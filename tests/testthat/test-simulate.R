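test_that("stimulus scripts follow their task definitions", {
  geom <- test_geom()
  fxs <- make_stimulus("FXS", 15, geom)
  expect_equal(nrow(fxs), 1)
  expect_equal(c(fxs$x, fxs$y), c(840, 525))

  hss <- make_stimulus("HSS", 10, geom, cadence_s = 1)
  expect_equal(nrow(hss), 10)
  expect_equal(length(unique(hss$y)), 1)
  expect_equal(length(unique(hss$x)), 2)
  expect_true(all(diff(hss$onset_s) == 1))
  # strict alternation
  expect_true(all(hss$x[-1] != hss$x[-10]))

  r1 <- make_stimulus("RAN", 8, geom, seed = 42)
  r2 <- make_stimulus("RAN", 8, geom, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$x >= 0 & r1$x <= geom$width_px))
  expect_true(all(r1$y >= 0 & r1$y <= geom$height_px))

  tex <- make_stimulus("TEX", 10, geom, seed = 1)
  expect_gt(nrow(tex), 20)
  expect_error(make_stimulus("XYZ", 5, geom))
})

test_that("noise-free fixation simulates to a constant, single-fixation trace", {
  geom <- test_geom()
  p <- subject_params(tremor_sd = 0, drift_rate = 0, blink_rate = 0)
  rec <- simulate_recording(make_stimulus("FXS", 2, geom), p, geom, seed = 1)
  expect_lt(diff(range(rec$theta_x)), 1e-12)
  ev <- classify_ivt(velocity_trace(rec, geom))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$kind, "fixation")
})

test_that("saccade count matches stimulus transitions across seeds", {
  geom <- test_geom()
  hits <- 0
  for (s in 1:20) {
    script <- make_stimulus("HSS", 5, geom, seed = s)
    rec <- simulate_recording(script, subject_params(blink_rate = 0),
                              geom, seed = s)
    ev <- classify_ivt(velocity_trace(rec, geom))
    n_sac <- sum(ev$kind == "saccade")
    if (abs(n_sac - (nrow(script) - 1)) <= 1) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("fixation velocities stay almost entirely below 100 deg/s", {
  geom <- test_geom()
  for (ts in c(0.05, 0.1)) {
    p <- subject_params(tremor_sd = ts, drift_rate = 0.02, blink_rate = 0)
    rec <- simulate_recording(make_stimulus("FXS", 10, geom), p, geom,
                              seed = 31)
    tr <- velocity_trace(rec, geom)
    expect_gte(mean(tr$velocity < 100, na.rm = TRUE), 0.99)
  }
})

test_that("simulated saccade peak velocities respect the main-sequence floor", {
  amps <- seq(2, 25, by = 0.5)
  vp <- gazeauth:::.main_sequence_vpeak(amps, 1)
  expect_true(all(vp >= 320))
  # and the realized trace peaks above the 300 deg/s detection threshold
  geom <- test_geom()
  rec <- simulate_recording(make_stimulus("HSS", 4, geom),
                            subject_params(blink_rate = 0), geom, seed = 6)
  tr <- velocity_trace(rec, geom)
  ev <- classify_ivt(tr)
  for (i in which(ev$kind == "saccade"))
    expect_gte(max(tr$velocity[ev$start[i]:(ev$end[i] - 1)]), 300)
})

test_that("blink counts follow the Poisson rate", {
  geom <- test_geom()
  rate <- 30  # per minute
  p <- subject_params(blink_rate = rate, tremor_sd = 0.02)
  counts <- vapply(1:30, function(s) {
    rec <- simulate_recording(make_stimulus("FXS", 20, geom), p, geom,
                              seed = 200 + s)
    nrow(extract_blinks(rec))
  }, numeric(1))
  lambda <- rate * 20 / 60
  se <- sqrt(lambda / 30)
  expect_lt(abs(mean(counts) - lambda), 3 * se + 0.3)
})

test_that("simulation is deterministic given the seed", {
  geom <- test_geom()
  p <- subject_params()
  s <- make_stimulus("RAN", 3, geom, seed = 5)
  r1 <- simulate_recording(s, p, geom, seed = 77)
  r2 <- simulate_recording(s, p, geom, seed = 77)
  expect_identical(r1$theta_x, r2$theta_x)
  expect_identical(r1$valid, r2$valid)
})

test_that("attention drift reproduces a prescribed gamma(t) law", {
  geom <- test_geom()
  drift <- function(t) (t / 12)^2
  recs <- lapply(1:12, function(i)
    simulate_recording(make_stimulus("FXS", 15, geom),
                       subject_params(seed = i), geom,
                       attention_drift = drift, seed = 300 + i))
  ap <- attention_profile(recs, geom)
  expect_false(is.na(ap$crossing_time))
  expect_lt(abs(ap$crossing_time - 12), 1.5)
})

test_that("cohorts have the expected structure and reproducible manifests", {
  geom <- test_geom()
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- simulate_cohort(3, d1, tasks = "HSS", rounds = 2, sessions = 2,
                        recording_s = 2, master_seed = 8)
  m2 <- simulate_cohort(3, d2, tasks = "HSS", rounds = 2, sessions = 2,
                        recording_s = 2, master_seed = 8)
  expect_equal(length(m1$recordings), 3 * 2 * 2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # the round/session grid mirrors the 31 x 8 x 2 test-cohort layout:
  # n_subjects * rounds * sessions recordings per task
  man <- read_manifest(d1)
  expect_equal(nrow(man$recordings), 12)
  expect_true(all(file.exists(man$recordings$path)))
  expect_error(simulate_cohort(1, tempfile()), "at least 2")
})
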