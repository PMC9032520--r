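test_that("step distance and direction match their closed forms", {
  expect_equal(step_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(step_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(step_direction(c(0, 0), c(0, 1)), 0)
  expect_equal(step_direction(c(0, 0), c(1, 1)), pi / 4)
  expect_equal(step_direction(c(0, 0), c(-1, 0)), 3 * pi / 2)
  expect_equal(step_direction(c(5, 5), c(5, 5)), 0)  # zero-length step
})

test_that("step distance agrees with a loop oracle on random pairs", {
  set.seed(5)
  p <- matrix(runif(2000, -100, 100), ncol = 2)
  q <- matrix(runif(2000, -100, 100), ncol = 2)
  for (i in sample(1000, 50)) {
    oracle <- sqrt((q[i, 1] - p[i, 1])^2 + (q[i, 2] - p[i, 2])^2)
    expect_identical(step_distance(p[i, ], q[i, ]), oracle)
  }
})

test_that("direction is always in [0, 2pi) and shifts by pi/2 under rotation", {
  set.seed(6)
  for (i in 1:200) {
    p <- runif(2, -10, 10)
    q <- runif(2, -10, 10)
    th <- step_direction(p, q)
    expect_gte(th, 0)
    expect_lt(th, 2 * pi)
    # rotation (x, y) -> (y, -x) about any centre advances theta by pi/2
    ctr <- runif(2, -5, 5)
    rot <- function(v) ctr + c(v[2] - ctr[2], -(v[1] - ctr[1]))
    th_rot <- step_direction(rot(p), rot(q))
    expect_equal((th + pi / 2) %% (2 * pi), th_rot %% (2 * pi),
                 tolerance = 1e-9)
  }
})

test_that("build_mi produces the documented shape and z-scored channels", {
  set.seed(7)
  n <- 500
  tr <- pixel_trace(cumsum(rnorm(n)), cumsum(rnorm(n)))
  mi <- build_mi(tr, target_len = 600)
  expect_equal(dim(mi$channels), c(2, 599))
  expect_equal(mi$valid_length, n - 1)
  live <- mi$channels[, seq_len(n - 1)]
  expect_lt(abs(mean(live[1, ])), 1e-9)
  expect_lt(abs(stats::sd(live[1, ]) - 1), 1e-9)
  expect_lt(abs(mean(live[2, ])), 1e-9)
  expect_lt(abs(stats::sd(live[2, ]) - 1), 1e-9)
  # padding is exactly zero
  expect_true(all(mi$channels[, n:599] == 0))
})

test_that("a 5 s fully valid 1000 Hz trace yields a 2 x 4999 feature", {
  set.seed(8)
  tr <- pixel_trace(cumsum(rnorm(5000)), cumsum(rnorm(5000)))
  mi <- build_mi(tr)
  expect_equal(dim(mi$channels), c(2, 4999))
})

test_that("constant traces z-score to all zeros", {
  tr <- pixel_trace(rep(3, 100), rep(4, 100))
  mi <- build_mi(tr)
  expect_true(all(mi$channels == 0))
})

test_that("circular scanpaths give constant distance and ramping direction", {
  t <- seq(0, 2 * pi, length.out = 401)[-401]
  tr <- pixel_trace(100 * cos(t) + 500, 100 * sin(t) + 500)
  ch <- gazeauth:::.step_channels(tr$x, tr$y)
  expect_lt(diff(range(ch$L)), 1e-9)
  # per-step loop oracle
  for (i in sample(399, 25)) {
    expect_equal(ch$L[i], step_distance(c(tr$x[i], tr$y[i]),
                                        c(tr$x[i + 1], tr$y[i + 1])))
    expect_equal(ch$theta[i], step_direction(c(tr$x[i], tr$y[i]),
                                             c(tr$x[i + 1], tr$y[i + 1])))
  }
  # direction advances uniformly mod 2pi
  d <- diff(ch$theta) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_lt(diff(range(d)), 1e-9)
})

test_that("distance channel is translation invariant", {
  set.seed(9)
  x <- cumsum(rnorm(200))
  y <- cumsum(rnorm(200))
  a <- gazeauth:::.step_channels(x, y)
  b <- gazeauth:::.step_channels(x + 123, y - 456)
  expect_equal(a$L, b$L, tolerance = 1e-9)
})

test_that("build_mi equals a naive two-pass oracle on random gappy traces", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(50:150, 1)
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    drop <- sample(n, sample(0:10, 1))
    x[drop] <- NA
    y[drop] <- NA
    tr <- pixel_trace(x, y)
    if (sum(tr$valid) < 3) next
    pairs_ok <- which(tr$valid[-n] & tr$valid[-1])
    if (length(pairs_ok) < 2) next
    mi <- build_mi(tr, target_len = n)
    # naive oracle: explicit loop then z-score
    L <- th <- numeric(0)
    for (i in pairs_ok) {
      L <- c(L, step_distance(c(x[i], y[i]), c(x[i + 1], y[i + 1])))
      th <- c(th, step_direction(c(x[i], y[i]), c(x[i + 1], y[i + 1])))
    }
    z <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
    expect_equal(mi$channels[1, seq_along(L)], z(L), tolerance = 1e-12)
    expect_equal(mi$channels[2, seq_along(L)], z(th), tolerance = 1e-12)
    expect_equal(mi$valid_length, length(L))
  }
})

test_that("build_mi rejects traces without consecutive valid samples", {
  tr <- pixel_trace(c(1, NA, 2, NA, 3), c(1, NA, 2, NA, 3))
  expect_error(build_mi(tr), "consecutive valid")
})
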