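test_that("mean-baseline dF/F matches closed-form fixtures", {
  # constant trace -> all zeros
  expect_equal(unique(as.numeric(dff_mean_baseline(toy_recording())$dff)),
               0)
  # trace (2, 4), baseline mean 3 -> (-1/3, 1/3)
  rec <- fluorescence_recording(matrix(c(2, 4), 1, 2))
  expect_equal(as.numeric(dff_mean_baseline(rec)$dff), c(-1 / 3, 1 / 3))
  # explicit baseline window
  rec2 <- fluorescence_recording(matrix(c(2, 2, 6), 1, 3))
  expect_equal(as.numeric(dff_mean_baseline(rec2, c(0, 2))$dff),
               c(0, 0, 2))
  # nonpositive baseline -> error naming the cell
  rec3 <- fluorescence_recording(matrix(c(0, 1, 0, 1), 2, 2))
  expect_error(dff_mean_baseline(rec3), "cell\\(s\\) 0")
})

test_that("percentile dF/F matches closed-form fixtures", {
  # 100-frame trace, minimum 10 once, then 20: under the interpolated
  # order-statistic convention p1 = 10 + 0.99 * (20 - 10) = 19.9
  raw <- matrix(c(10, rep(20, 99)), 1, 100)
  d <- dff_percentile(fluorescence_recording(raw))
  expect_equal(d$dff[1, 1], (10 - 19.9) / 19.9, tolerance = 1e-12)
  expect_equal(d$dff[1, 2], (20 - 19.9) / 19.9, tolerance = 1e-12)
  expect_equal(d$provenance$quantile_type, 7)
  expect_equal(unique(as.numeric(
    dff_percentile(toy_recording())$dff)), 0)
  expect_error(dff_percentile(fluorescence_recording(
    matrix(c(-5, 1, 1, 1), 1, 4))), "nonpositive")
})

test_that("both dF/F variants are scale invariant and offsets shrink range", {
  set.seed(1)
  for (i in 1:10) {
    raw <- matrix(abs(rnorm(200, 100, 20)) + 1, 4, 50)
    rec <- fluorescence_recording(raw)
    k <- runif(1, 0.1, 10)
    reck <- fluorescence_recording(raw * k)
    expect_equal(dff_mean_baseline(rec)$dff, dff_mean_baseline(reck)$dff,
                 tolerance = 1e-10)
    expect_equal(dff_percentile(rec)$dff, dff_percentile(reck)$dff,
                 tolerance = 1e-10)
    # baseline inflation: adding a positive offset shrinks dynamic range
    rec_off <- fluorescence_recording(raw + 50)
    expect_lt(diff(range(dff_percentile(rec_off)$dff)),
              diff(range(dff_percentile(rec)$dff)))
  }
})

test_that("Savitzky-Golay filter has the polynomial-reproduction property", {
  x <- rep(3.7, 100)
  expect_equal(savgol_smooth(x), x)
  # exact cubic reproduced in the interior
  t <- seq_len(200)
  cub <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  sm <- savgol_smooth(cub)
  expect_equal(sm[16:185], cub[16:185], tolerance = 1e-8)
  # commutes with adding constants
  set.seed(2)
  z <- rnorm(150)
  expect_equal(savgol_smooth(z + 5), savgol_smooth(z) + 5,
               tolerance = 1e-10)
  # reduces white-noise variance
  expect_lt(var(savgol_smooth(z)), var(z))
  # precondition checks
  expect_error(savgol_smooth(z, window_frames = 30), "odd")
  expect_error(savgol_smooth(z, window_frames = 3, polyorder = 3),
               "polyorder")
  expect_error(savgol_smooth(z[1:10], window_frames = 31), "length")
})

test_that("ratiometric correction behaves in both modes", {
  g <- c(0.2, 0.4); r <- c(0.1, 0.4)
  expect_equal(ratiometric_correct(g, r), c(0.1, 0))
  expect_equal(ratiometric_correct(g, rep(0, 2)), g)
  expect_equal(ratiometric_correct(g, g), c(0, 0))
  expect_equal(ratiometric_correct(g, r, mode = "divide"),
               (1 + g) / (1 + r) - 1)
  expect_error(ratiometric_correct(g, 0.1), "length")
})

test_that("subregion grid means match direct arithmetic", {
  # uniform image: every subregion trace is constant
  st <- array(7, c(32, 32, 3))
  out <- subregion_grid_means(st)
  expect_equal(dim(out), c(256L, 3L))
  expect_true(all(out == 7))
  # 32x32 image, 16x16 grid -> 2x2 tiles; hand-check one tile
  st2 <- array(0, c(32, 32, 1))
  st2[1:2, 3:4, 1] <- c(1, 2, 3, 4)   # tile (row 1, col 2)
  out2 <- subregion_grid_means(st2)
  expect_equal(out2[2, 1], mean(c(1, 2, 3, 4)))
  expect_equal(sum(out2 != 0), 1)     # single bright tile, one trace
  expect_error(subregion_grid_means(array(0, c(8, 8, 1)),
                                    grid = c(16, 16)), "exceeds")
})
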