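test_that("distraction distance is the mean distance to the stimulus", {
  expect_equal(distraction_distance(c(0, 0), c(0, 0), c(0, 0)), 0)
  # 3-4-5 triangles
  expect_equal(distraction_distance(c(3, 6), c(4, 8), c(0, 0)), 7.5)
  # brute-force mean over random points
  set.seed(3)
  x <- runif(100, -50, 50)
  y <- runif(100, -50, 50)
  target <- c(10, -5)
  oracle <- mean(vapply(seq_along(x), function(i)
    sqrt((x[i] - target[1])^2 + (y[i] - target[2])^2), numeric(1)))
  expect_identical(distraction_distance(x, y, target), oracle)
  expect_error(distraction_distance(NA_real_, NA_real_, c(0, 0)), "valid")
})

test_that("blink fraction is the invalid-sample average, with run count", {
  expect_equal(blink_fraction(rep(TRUE, 500))$fraction, 0)
  expect_equal(blink_fraction(c(rep(FALSE, 50), rep(TRUE, 450)))$fraction, 0.1)
  expect_equal(blink_fraction(rep(FALSE, 7))$fraction, 1)
  bf <- blink_fraction(c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(bf$runs, 2)
  expect_error(blink_fraction(logical(0)), "empty")
})

test_that("distraction angle matches its closed form and is monotone", {
  geom <- test_geom()
  expect_equal(distraction_angle(0, geom), 0)
  expect_equal(distraction_angle(100, geom),
               atan(100 * 297 / (1050 * 550)) * 180 / pi)
  expect_equal(distraction_angle(100, geom), 2.944, tolerance = 1e-3)
  # inverse construction: D chosen to land exactly on 1 degree
  d1 <- tan(pi / 180) * 1050 * 550 / 297
  expect_equal(distraction_angle(d1, geom), 1)
  d <- seq(0, 2000, by = 50)
  expect_true(all(diff(distraction_angle(d, geom)) > 0))
})

test_that("a 14 s analysis window yields 28 half-second windows", {
  geom <- test_geom()
  rec <- gaze_recording(rep(0, 15000), rep(0, 15000))
  ap <- attention_profile(rec, geom)
  expect_equal(nrow(ap$windows), 28)
})

test_that("constant gaze offset gives a flat profile with no crossing", {
  geom <- test_geom()
  # offset corresponding to 0.2 degrees
  off <- 0.2
  rec <- gaze_recording(rep(off, 15000), rep(0, 15000))
  ap <- attention_profile(rec, geom)
  expect_true(all(abs(ap$windows$gamma - ap$windows$gamma[1]) < 1e-6))
  expect_true(is.na(ap$crossing_time))
})

test_that("averaging identical recordings equals the single-recording profile", {
  geom <- test_geom()
  set.seed(4)
  th <- cumsum(rnorm(15000, 0, 0.001))
  rec <- gaze_recording(th, -th)
  ap1 <- attention_profile(rec, geom)
  apk <- attention_profile(list(rec, rec, rec), geom)
  expect_equal(ap1$windows$gamma, apk$windows$gamma, tolerance = 1e-12)
  expect_equal(ap1$windows$D, apk$windows$D, tolerance = 1e-12)
})

test_that("quadratic fits are recovered exactly from quadratic data", {
  # feed window means generated from a known quadratic through the fitter
  co <- c(0.05, -0.01, 0.008)
  profile <- structure(list(), class = "attention_profile")
  t <- seq(1.25, 14.75, by = 0.5)
  g <- co[1] + co[2] * t + co[3] * t^2
  fit <- stats::lm(g ~ t + I(t^2))
  expect_lt(max(abs(unname(coef(fit)) - co)), 1e-8)
  # crossing solved on the fitted polynomial
  cross <- gazeauth:::.quad_crossing(co, 1)
  expect_equal(co[1] + co[2] * cross + co[3] * cross^2, 1, tolerance = 1e-9)
})

test_that("crossing-time solver handles linear and degenerate cases", {
  expect_equal(gazeauth:::.quad_crossing(c(0, 0.1, 0), 1), 10)
  expect_true(is.na(gazeauth:::.quad_crossing(c(0.2, -0.01, 0), 1)))
  expect_equal(gazeauth:::.quad_crossing(c(2, 0, 0.1), 1), 0)
})

test_that("windows with only invalid samples still contribute P = 1", {
  geom <- test_geom()
  th <- rep(0, 15000)
  th[1501:2000] <- NA  # exactly the second analysis window (after 1 s trim)
  rec <- gaze_recording(th, rep(0, 15000))
  ap <- attention_profile(rec, geom)
  expect_equal(ap$windows$P[2], 1)
  expect_true(is.nan(ap$windows$gamma[2]) || is.na(ap$windows$gamma[2]))
  expect_equal(ap$windows$P[1], 0)
  expect_equal(ap$windows$P[3], 0)
})

test_that("short recordings are skipped with a warning", {
  geom <- test_geom()
  short <- gaze_recording(rep(0, 5000), rep(0, 5000))
  ok <- gaze_recording(rep(0, 15000), rep(0, 15000))
  expect_warning(ap <- attention_profile(list(short, ok), geom), "skipped")
  expect_equal(ap$n_recordings, 1)
  expect_error(suppressWarnings(attention_profile(list(short), geom)),
               "no usable")
})
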