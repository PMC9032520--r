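test_that("saccade extent filter implements the drop rule", {
  expect_false(filter_saccade(5, 5))                       # single point
  expect_true(filter_saccade(c(0, 200), c(10, 10)))        # wide, flat sweep
  set.seed(11)
  expect_false(filter_saccade(runif(20, 0, 5), runif(20, 0, 5)))  # jitter blob
  # "either" mode drops the flat sweep because its height is short
  expect_false(filter_saccade(c(0, 200), c(10, 10), mode = "either"))
})

test_that("rasterization counts every valid sample once", {
  n <- 30
  tr <- pixel_trace(seq(10, 300, length.out = n), rep(20, n))
  r <- rasterize_saccades(one_saccade_events(n), tr, canvas = c(400, 50))
  expect_equal(sum(r$counts), n)
  expect_equal(r$n_saccades_used, 1)
  # zero saccades
  ev0 <- data.frame(kind = "fixation", start = 1L, end = n + 1L,
                    duration_ms = n)
  expect_equal(sum(rasterize_saccades(ev0, tr, canvas = c(400, 50))$counts), 0)
})

test_that("overlapping saccades accumulate; oracle agreement", {
  set.seed(12)
  n <- 40
  x <- c(seq(5, 80, length.out = 20), seq(80, 5, length.out = 20))
  y <- c(seq(5, 40, length.out = 20), seq(40, 5, length.out = 20))
  ev <- data.frame(kind = c("saccade", "saccade"),
                   start = c(1L, 21L), end = c(21L, 41L),
                   duration_ms = c(20, 20))
  tr <- pixel_trace(x, y)
  r <- rasterize_saccades(ev, tr, canvas = c(100, 50), min_extent_px = 10)
  # dictionary-accumulation oracle
  px <- pmin(pmax(round(x), 0), 99) + 1
  py <- pmin(pmax(round(y), 0), 49) + 1
  key <- paste(py, px)
  tab <- table(key)
  for (k in names(tab)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    expect_equal(r$counts[ij[1], ij[2]], as.numeric(tab[[k]]))
  }
  expect_equal(sum(r$counts), 40)
})

test_that("off-canvas samples clip to the border", {
  tr <- pixel_trace(c(-50, 500), c(-20, 300))
  r <- rasterize_saccades(one_saccade_events(2), tr, canvas = c(100, 60))
  expect_equal(r$counts[1, 1], 1)
  expect_equal(r$counts[60, 100], 1)
})

test_that("translation moves the count grid rigidly", {
  set.seed(13)
  n <- 25
  x <- seq(20, 60, length.out = n)
  y <- seq(30, 50, length.out = n)
  tr1 <- pixel_trace(x, y)
  tr2 <- pixel_trace(x + 7, y + 4)
  r1 <- rasterize_saccades(one_saccade_events(n), tr1, canvas = c(100, 100))
  r2 <- rasterize_saccades(one_saccade_events(n), tr2, canvas = c(100, 100))
  expect_equal(r2$counts[5:100, 8:100], r1$counts[1:96, 1:93])
})

test_that("finalized SDMs are probability images", {
  set.seed(14)
  counts <- matrix(rpois(1680 * 1050 / 100, 0.1), 105, 168)
  sdm <- finalize_sdm(counts, size = 32)
  expect_true(all(sdm$grid >= 0))
  expect_lt(abs(sum(sdm$grid) - 1), 1e-9)
  # uniform input stays uniform
  u <- finalize_sdm(matrix(1, 50, 80), size = 16)
  expect_lt(diff(range(u$grid)), 1e-12)
  expect_equal(u$grid[1, 1], 1 / 256)
  # zero input allowed only as the empty map
  z <- finalize_sdm(matrix(0, 50, 80), size = 16)
  expect_true(all(z$grid == 0))
  expect_equal(z$n_saccades_used, 0L)
  expect_error(finalize_sdm(matrix(-1, 4, 4)), "nonnegative")
})

test_that("area downscaling matches an exact block-average oracle", {
  # canvas 16 x 10 -> 4 x 4: x blocks of 4, y blocks of 2.5
  counts <- matrix(0, 10, 16)
  counts[3, 7] <- 12  # single hot cell
  sdm <- finalize_sdm(counts, size = 4)
  expect_lt(abs(sum(sdm$grid) - 1), 1e-12)
  # y cell 3 spans output rows [0.8, 1.2] -> half in row 1, half in row 2;
  # x cell 7 spans output cols [1.5, 1.75] -> all in col 2
  expect_equal(sdm$grid[1, 2], 0.5)
  expect_equal(sdm$grid[2, 2], 0.5)
  expect_equal(sum(sdm$grid != 0), 2)
  # integer-ratio case: exact block sums
  set.seed(15)
  c2 <- matrix(runif(80), 8, 10)
  s2 <- finalize_sdm(c2, size = 2)
  oracle <- rbind(c(sum(c2[1:4, 1:5]), sum(c2[1:4, 6:10])),
                  c(sum(c2[5:8, 1:5]), sum(c2[5:8, 6:10]))) / sum(c2)
  expect_equal(s2$grid, oracle, tolerance = 1e-12)
})

test_that("mass is preserved through downscaling for random inputs", {
  set.seed(16)
  for (i in 1:20) {
    nr <- sample(20:90, 1)
    nc <- sample(20:90, 1)
    counts <- matrix(rpois(nr * nc, 0.3), nr, nc)
    if (sum(counts) == 0) next
    A <- gazeauth:::.area_weights(13, nr)
    B <- gazeauth:::.area_weights(13, nc)
    down <- A %*% counts %*% t(B)
    expect_lt(abs(sum(down) - sum(counts)), 1e-9 * sum(counts))
    sdm <- finalize_sdm(counts, size = 13)
    expect_lt(abs(sum(sdm$grid) - 1), 1e-9)
  }
})
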