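test_that("pairwise correlations match the textbook formula", {
  t <- seq(0, 1, length.out = 50)
  m <- rbind(sin(2 * pi * t), -sin(2 * pi * t), cos(2 * pi * t),
             sin(2 * pi * t) + 0.5)
  r <- pairwise_correlations(as_dff(m))
  expect_equal(diag(r), rep(1, 4))
  expect_equal(r, t(r))
  expect_equal(r[1, 2], -1)
  expect_equal(r[1, 4], 1)    # affine rescaling leaves r unchanged
  # hand computation for an arbitrary pair
  hand <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_equal(r[1, 3], hand(m[1, ], m[3, ]))
  # zero-variance cells are excluded with a message, not an error
  m2 <- rbind(m, rep(3, 50))
  expect_message(r2 <- pairwise_correlations(as_dff(m2)), "zero-variance")
  expect_true(all(is.na(r2[5, ])))
  expect_error(pairwise_correlations(as_dff(matrix(1, 3, 10))),
               "all cells")
})

test_that("correlation-by-distance bins pairs correctly", {
  coords <- rbind(c(0, 0), c(10, 0), c(50, 0))
  corr <- matrix(1, 3, 3)
  cvd <- correlation_vs_distance(corr, coords)
  expect_equal(cvd$bin_low_um[1], 0)
  expect_equal(cvd$n_pairs[1], 1L)       # the 10 um pair
  expect_equal(cvd$mean_correlation[1], 1)
  expect_equal(cvd$n_pairs[2], 2L)       # 40 and 50 um pairs
  # pairs only at 50 um: bin [0,40) empty and flagged missing
  cvd2 <- correlation_vs_distance(matrix(1, 2, 2),
                                  rbind(c(0, 0), c(50, 0)))
  expect_true(is.na(cvd2$mean_correlation[1]))
  expect_equal(cvd2$n_pairs[1], 0L)
})

test_that("KS comparison of dF/F distributions matches the normal shift", {
  x <- matrix(rnorm(10000), 10, 1000)
  same <- cumulative_dff_comparison(x, x)
  expect_equal(same$ks_statistic, 0)
  # N(0,1) vs N(0,1)+1: D = 2*pnorm(0.5) - 1 = 0.3829
  set.seed(3)
  a <- rnorm(1e4); b <- rnorm(1e4) + 1
  ks <- cumulative_dff_comparison(a, b)
  expect_equal(ks$ks_statistic, 2 * pnorm(0.5) - 1, tolerance = 0.05)
  # left-shifted sample's CDF lies above pointwise
  grid <- seq(-2, 2, by = 0.1)
  expect_true(all(ks$ecdf_a(grid) >= ks$ecdf_b(grid)))
})

test_that("stimulus-triggered averages recover planted responses", {
  fs <- 30
  dffm <- matrix(0, 5, 3000)
  kern <- c(rep(1, 15), rep(0.5, 15))
  onsets <- c(300, 900, 1500, 2100)
  for (on in onsets) dffm[, (on + 1):(on + 30)] <- rep(kern, each = 5)
  sl <- stimulus_log(onsets, rep("airpuff", 4))
  sta <- stimulus_triggered_average(as_dff(dffm), sl, pre_s = 1,
                                    post_s = 2)
  expect_equal(sta$airpuff$n_trials, 4L)
  post <- sta$airpuff$mean[sta$airpuff$time_s >= 0]
  expect_equal(post[1:30], kern, tolerance = 1e-12)
  expect_equal(max(sta$airpuff$sem), 0)   # identical trials
  # edge trials are dropped with a message
  sl2 <- stimulus_log(c(10, 900), c("airpuff", "airpuff"))
  expect_message(stimulus_triggered_average(as_dff(dffm), sl2,
                                            pre_s = 1, post_s = 2),
                 "dropped 1")
})

test_that("response amplitude is the post-window maximum only", {
  fs <- 30
  dffm <- matrix(0, 1, 2000)
  dffm[1, 101:110] <- 0.7               # boxcar inside the window
  dffm[1, 100 + 21 * fs] <- 9           # peak at 21 s, outside 20 s window
  sl <- stimulus_log(100, "airpuff")
  ra <- response_amplitude(as_dff(dffm), sl, window_s = 20)
  expect_equal(ra$amplitude, 0.7)
  ra0 <- response_amplitude(as_dff(matrix(0, 1, 2000)), sl)
  expect_equal(ra0$amplitude, 0)
})

test_that("responsiveness testing gates on normality and applies BH", {
  fs <- 30
  set.seed(11)
  n_tr <- 10
  onsets <- seq(100, by = 200, length.out = n_tr)
  sl <- stimulus_log(onsets, rep("airpuff", n_tr))
  # cell 1 responds (+1 shift after onset), cells 2-20 are null
  dffm <- matrix(rnorm(20 * 2200, 0, 0.1), 20, 2200)
  for (on in onsets) dffm[1, (on + 1):(on + fs)] <-
    dffm[1, (on + 1):(on + fs)] + 1
  rt <- responsiveness_test(as_dff(dffm), sl)
  expect_true(rt$responsive[rt$cell == 0])
  expect_lt(mean(rt$responsive[rt$cell != 0]), 0.2)
  expect_true(all(rt$p_adj >= rt$p_raw))
  expect_equal(attr(rt, "recruitment")[["airpuff"]], mean(rt$responsive))
  # single tested cell: BH adjustment equals the raw p
  rt1 <- responsiveness_test(as_dff(dffm[1, , drop = FALSE]), sl)
  expect_equal(rt1$p_adj, rt1$p_raw)
  expect_error(responsiveness_test(as_dff(dffm),
                                   stimulus_log(100, "airpuff")),
               ">= 2")
})

test_that("interneuron identification flags the bright tail", {
  # 100 cells, 3 bright: exactly those three at the 97th percentile
  red <- fluorescence_recording(
    matrix(c(rep(100, 3), rep(1, 97)), 100, 30), channel = "red")
  mask <- identify_interneurons(red)
  expect_equal(which(mask), 1:3)
  # all-identical cells: everyone ties at the percentile (>= rule)
  red2 <- toy_recording(10, 10)
  expect_message(m2 <- identify_interneurons(red2), "degenerate")
  expect_true(all(m2))
})

test_that("cell-neuropil correlation handles the degenerate cases", {
  x <- rnorm(1000)
  expect_equal(cell_neuropil_correlation(x, x), 1)
  expect_equal(cell_neuropil_correlation(x, -x), -1)
  set.seed(5)
  expect_lt(abs(cell_neuropil_correlation(rnorm(1e4), rnorm(1e4))), 0.05)
  expect_warning(r <- cell_neuropil_correlation(rep(1, 10), rnorm(10)),
                 "zero-variance")
  expect_true(is.na(r))
  expect_error(cell_neuropil_correlation(1:5, 1:6), "length")
})
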