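test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_cells = 20, duration_s = 30, seed = 5)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$raw, b$recording$raw)
  expect_identical(a$red$raw, b$red$raw)
  expect_identical(a$truth, b$truth)
  # different seed changes the data
  c <- simulate_recording(sim_config(n_cells = 20, duration_s = 30,
                                     seed = 6))
  expect_false(identical(a$recording$raw, c$recording$raw))
})

test_that("adding cells does not perturb event timing (substreams)", {
  a <- simulate_recording(sim_config(n_cells = 20, duration_s = 60,
                                     seed = 2))
  b <- simulate_recording(sim_config(n_cells = 40, duration_s = 60,
                                     seed = 2))
  expect_identical(a$truth$events$onset_frame, b$truth$events$onset_frame)
})

test_that("planted events recruit the configured fraction of cells", {
  sched <- data.frame(time_s = c(10, 30), duration_s = c(1, 1),
                      participation = c(1.0, 0.5), amplitude = c(1, 1))
  cfg <- sim_config(n_cells = 40, duration_s = 60, noise_sd = 0,
                    shared_sd = 0, event_schedule = sched, seed = 1)
  sim <- simulate_recording(cfg)
  expect_equal(length(sim$truth$participants[[1]]), 40)
  expect_equal(length(sim$truth$participants[[2]]), 20)
  # full-participation event: every cell shows a transient at the peak
  pk <- sim$truth$events$peak_frame[1] + 1
  dff <- dff_percentile(sim$recording)
  expect_true(all(dff$dff[, pk] > 0.5))
  # participation by the detector's own rule on noiseless traces
  ev <- detect_events(dff)
  mt <- match_events(ev, sim$truth$events, frame_rate = 30)
  expect_true(all(abs(mt$participation_detected - mt$participation)
                  <= 1 / 40))
})

test_that("schedules past the recording end are rejected", {
  sched <- data.frame(time_s = 55, duration_s = 10, participation = 1,
                      amplitude = 1)
  expect_error(sim_config(n_cells = 5, duration_s = 60,
                          event_schedule = sched), "past recording")
  expect_error(sim_config(participation_range = c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("noiseless, eventless recordings are constant per cell", {
  cfg <- sim_config(n_cells = 5, duration_s = 10, noise_sd = 0,
                    shared_sd = 0, event_rate_per_min = 0, seed = 1)
  sim <- simulate_recording(cfg)
  expect_equal(max(apply(sim$recording$raw, 1, sd)), 0)
})

test_that("pairwise correlation decays with distance when shared noise is on", {
  cfg <- sim_config(n_cells = 120, duration_s = 120, noise_sd = 0.03,
                    shared_sd = 0.05, spatial_corr_length_um = 80,
                    event_rate_per_min = 0, seed = 4)
  sim <- simulate_recording(cfg)
  corr <- pairwise_correlations(dff_mean_baseline(sim$recording))
  cvd <- correlation_vs_distance(corr, sim$recording$coords)
  m <- cvd$mean_correlation[cvd$n_pairs >= 20]
  # monotone decreasing trend over populated 40 um bins
  expect_gt(m[1], m[length(m)])
  expect_lt(mean(diff(m)), 0)
})

test_that("movement generator honours the bout plan", {
  cfg <- sim_config(seed = 9)
  qs <- simulate_movement(cfg, data.frame(state = "QS", duration_s = 60))
  d <- movement_from_pose(qs$pose)$displacement
  expect_true(all(d < 1.0))  # below the immobility threshold everywhere

  wk <- simulate_movement(cfg, data.frame(state = "wake",
                                          duration_s = 30))
  dw <- movement_from_pose(wk$pose)$displacement
  expect_gte(mean(dw >= 1.0), 0.95)

  # AS twitch count equals the seeded Poisson realisation, about
  # rate * duration on average
  as <- simulate_movement(sim_config(seed = 10, twitch_rate_hz = 0.2),
                          data.frame(state = "AS", duration_s = 60))
  expect_equal(length(as$truth$twitch_frames), 14)  # frozen at seed 10
  rates <- vapply(1:30, function(s) {
    mv <- simulate_movement(sim_config(seed = s, twitch_rate_hz = 0.2),
                            data.frame(state = "AS", duration_s = 60))
    length(mv$truth$twitch_frames)
  }, 0)
  expect_gt(mean(rates), 8); expect_lt(mean(rates), 16)
})

test_that("serotonin trace follows state offsets and stimulus transients", {
  cfg <- sim_config(serotonin_noise_sd = 0, seed = 1)
  states <- rep(c("wake", "QS", "AS"), each = 100)
  tr <- simulate_serotonin(cfg, states)
  expect_equal(unique(tr[1:100]), 1.0)
  expect_equal(unique(tr[101:200]), 0.5)
  expect_equal(unique(tr[201:300]), 0.0)

  sl <- stimulus_log(150, "airpuff")
  tr2 <- simulate_serotonin(cfg, states, sl)
  expect_equal(max(tr2[151:200] - tr[151:200]), cfg$serotonin_stim_amp,
               tolerance = 1e-9)
  # zero-amplitude stimuli leave the trace unchanged
  cfg0 <- sim_config(serotonin_noise_sd = 0, serotonin_stim_amp = 0)
  expect_identical(simulate_serotonin(cfg0, states, sl),
                   simulate_serotonin(cfg0, states))
})

test_that("LSPS simulation plants charges where asked and errors off-grid", {
  m <- simulate_lsps_map(toy_layers(),
                         data.frame(row = 7, col = 8, charge = 2.5))
  expect_equal(sum(m != 0), 1)
  expect_equal(m[8, 9], 2.5)
  m0 <- simulate_lsps_map(toy_layers(), NULL)
  expect_true(all(m0 == 0))
  expect_error(simulate_lsps_map(toy_layers(),
                                 data.frame(row = 11, col = 0, charge = 1)),
               "outside")
  # planted L5b block shows up in the layer sum
  pl <- data.frame(row = c(7, 8), col = c(3, 4), charge = c(1, 2))
  m2 <- simulate_lsps_map(toy_layers(), pl)
  expect_equal(unname(layer_input_sums(m2)["L5b"]), 3)
})
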