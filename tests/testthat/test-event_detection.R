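test_that("population mean trace is the unweighted cell mean", {
  expect_equal(population_mean_trace(as_dff(rbind(c(0, 2), c(2, 0)))),
               c(1, 1))
  m <- matrix(rnorm(20), 1, 20)
  expect_equal(population_mean_trace(as_dff(m)), as.numeric(m))
  expect_equal(population_mean_trace(as_dff(matrix(0, 4, 6))), rep(0, 6))
})

test_that("a flat recording yields no events", {
  ev <- detect_events(as_dff(matrix(5, 4, 600)))
  expect_equal(nrow(ev), 0L)
})

test_that("a planted boxcar transient is recovered exactly", {
  rec <- boxcar_recording(n_cells = 10, onset = 300, dur = 60)
  dff <- dff_percentile(rec)
  ev <- detect_events(dff)
  expect_equal(nrow(ev), 1L)
  # half-open interval brackets the boxcar (threshold crossing at onset)
  expect_equal(ev$start_frame, 299L)
  expect_equal(ev$end_frame, 359L)
  expect_equal(ev$participation, 1.0)
  expect_equal(ev$event_class, "H")
  expect_false(ev$truncated)

  # 50% of cells driven -> participation 0.5, class L
  rec2 <- boxcar_recording(n_cells = 10, cells = 1:5)
  ev2 <- detect_events(dff_percentile(rec2))
  expect_equal(ev2$participation, 0.5)
  expect_equal(ev2$event_class, "L")
})

test_that("two separated transients give two ordered, disjoint events", {
  raw <- matrix(100, 8, 3600)
  raw[, 600:660] <- 250
  raw[, 1500:1560] <- 300
  ev <- detect_events(dff_percentile(fluorescence_recording(raw)))
  expect_equal(nrow(ev), 2L)
  expect_true(ev$end_frame[1] <= ev$start_frame[2])
  expect_equal(ev$peak_frame, sort(ev$peak_frame))
})

test_that("participation uses a strict within-vs-whole mean comparison", {
  # constant cell: equality, so it must not participate
  m <- rbind(rep(1, 100), c(rep(0, 40), rep(5, 20), rep(0, 40)))
  sp <- score_participation(as_dff(m), 40, 60)
  expect_false(sp$participant_mask[1])
  expect_true(sp$participant_mask[2])
  expect_equal(sp$participation, 0.5)
  expect_error(score_participation(as_dff(m), 50, 50), "empty")
})

test_that("classification thresholds follow the H/L participation rules", {
  expect_equal(classify_event(0.85), "H")
  expect_equal(classify_event(0.50), "L")
  expect_equal(classify_event(0.10), "unclassified")
  # boundary conventions: strict > for H, inclusive L bounds
  expect_equal(classify_event(c(0.80, 0.20)), c("L", "L"))
  expect_error(classify_event(1.2))
})

test_that("event summaries stratify by class and compute frequency", {
  rec <- boxcar_recording(n_cells = 10, n_frames = 18000, onset = 3000)
  dff <- dff_percentile(rec)
  ev <- detect_events(dff)
  s <- summarize_events(ev, 600)
  expect_equal(s$frequency_per_min[s$event_class == "H"], 1 / 10)
  expect_equal(s$n[s$event_class == "all"], 1L)
  s0 <- summarize_events(detect_events(as_dff(matrix(1, 2, 600))), 600)
  expect_true(all(s0$n == 0))
  expect_true(all(is.na(s0$mean_amplitude)))
})

test_that("interval detector matches the brute-force reference on random data", {
  res <- evaluate_event_oracle(n_recordings = 25, seed = 42)
  expect_equal(res$agreement, 1.0)
})

test_that("detection is time-translation equivariant away from edges", {
  set.seed(7)
  base <- matrix(abs(rnorm(6 * 1200, 100, 10)) + 1, 6, 1200)
  base[, 400:430] <- base[, 400:430] * 2
  k <- 90
  shifted <- cbind(base[, (k + 1):1200], base[, 1:k])
  e1 <- detect_events(dff_percentile(fluorescence_recording(base)))
  e2 <- detect_events(dff_percentile(fluorescence_recording(shifted)))
  inner1 <- e1[!e1$truncated & e1$start_frame >= k, ]
  match2 <- e2[match(inner1$peak_frame - k, e2$peak_frame), ]
  expect_equal(match2$start_frame, inner1$start_frame - k)
  expect_equal(match2$end_frame, inner1$end_frame - k)
})

test_that("binned scan agrees with the interval method on separated events", {
  rec <- boxcar_recording(n_cells = 10, n_frames = 3600, onset = 600)
  dff <- dff_percentile(rec)
  a <- detect_events(dff, method = "interval")
  b <- detect_events(dff, method = "binned")
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_error(detect_events(as_dff(matrix(1, 2, 30)), bin_s = 6),
               "longer than recording")
})

test_that("every event gets exactly one class and counts partition", {
  sim <- simulate_recording(sim_config(n_cells = 50, duration_s = 180,
                                       seed = 13))
  ev <- detect_events(dff_percentile(sim$recording))
  expect_true(all(ev$event_class %in% c("H", "L", "unclassified")))
  s <- summarize_events(ev, 180)
  expect_equal(sum(s$n[s$event_class != "all"]),
               s$n[s$event_class == "all"])
})
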