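test_that("movement is the Euclidean displacement of consecutive frames", {
  pose <- data.frame(frame = 0:1, marker = "left_forelimb",
                     x = c(0, 3), y = c(0, 4), likelihood = 1)
  mv <- movement_from_pose(pose)
  expect_equal(as.numeric(mv$displacement), 5)
  # stationary marker
  pose2 <- data.frame(frame = 0:9, marker = "left_forelimb",
                      x = 2, y = 3, likelihood = 1)
  expect_true(all(movement_from_pose(pose2)$displacement == 0))
  # pure x-translation at speed v
  pose3 <- data.frame(frame = 0:9, marker = "left_forelimb",
                      x = (0:9) * 1.5, y = 0, likelihood = 1)
  expect_true(all(abs(movement_from_pose(pose3)$displacement - 1.5)
                  < 1e-12))
  expect_error(movement_from_pose(pose3[1, ]), ">= 2 frames")
})

test_that("low-confidence points are interpolated over short gaps", {
  pose <- data.frame(frame = 0:29, marker = "left_forelimb",
                     x = 0:29, y = 0, likelihood = 1)
  pose$likelihood[10:12] <- 0.1   # 3-frame gap (< 0.5 s at 30 fps)
  mv <- movement_from_pose(pose)
  expect_true(all(abs(mv$displacement - 1) < 1e-9))
  pose$likelihood[5:29] <- 0.1    # long gap: unscorable frames reported
  expect_message(movement_from_pose(pose), "unscorable")
})

test_that("degenerate movement patterns score as single bouts", {
  mk_move <- function(d) {
    structure(list(displacement = matrix(d, ncol = 1,
                                         dimnames = list(NULL,
                                                         "left_forelimb")),
                   frame_rate = 30), class = "movement_trace")
  }
  b0 <- score_sleep_states(mk_move(rep(0, 900)))
  expect_equal(nrow(b0), 1L)
  expect_equal(b0$state, "QS")
  bw <- score_sleep_states(mk_move(rep(5, 900)))
  expect_equal(bw$state, "wake")
  expect_error(score_sleep_states(mk_move(rep(0, 900)), marker = "nose"),
               "no marker")
  expect_error(score_sleep_states(mk_move(rep(0, 900)),
                                  max_twitch_s = 2, min_wake_s = 1),
               "max_twitch_s")
})

test_that("bouts tile the recording and planted states are recovered", {
  cfg <- sim_config(seed = 21)
  plan <- data.frame(state = c("wake", "QS", "AS"),
                     duration_s = c(30, 60, 60))
  mv <- simulate_movement(cfg, plan)
  move <- movement_from_pose(mv$pose)
  bouts <- score_sleep_states(move)
  # tiling without overlap
  expect_equal(bouts$start_frame[1], 0L)
  expect_equal(bouts$start_frame[-1], bouts$end_frame[-nrow(bouts)])
  expect_equal(bouts$end_frame[nrow(bouts)], nrow(move$displacement))
  truth <- mv$truth$states[-length(mv$truth$states)]
  st <- attr(bouts, "states")
  expect_gte(mean(st == truth), 0.9)
})

test_that("scoring is invariant to uniform spatial rescaling", {
  cfg <- sim_config(seed = 22)
  plan <- data.frame(state = c("QS", "AS", "wake"),
                     duration_s = c(40, 40, 20))
  mv <- simulate_movement(cfg, plan)
  pose2 <- mv$pose
  pose2$x <- pose2$x * 3; pose2$y <- pose2$y * 3
  b1 <- score_sleep_states(movement_from_pose(mv$pose), theta_move = 1)
  b2 <- score_sleep_states(movement_from_pose(pose2), theta_move = 3)
  expect_identical(attr(b1, "states"), attr(b2, "states"))
})

test_that("state-conditioned signals report means and exact fractions", {
  cfg <- sim_config(serotonin_noise_sd = 0, seed = 1)
  states <- rep(c("wake", "QS", "AS"), times = c(100, 200, 100))
  tr <- simulate_serotonin(cfg, states)
  bouts <- structure(
    data.frame(state = c("wake", "QS", "AS"),
               start_frame = c(0L, 100L, 300L),
               end_frame = c(100L, 300L, 400L)),
    states = states, class = c("sleep_bouts", "data.frame"))
  sc <- state_conditioned_signal(tr, bouts)
  expect_equal(sc$mean_signal, c(1, 0.5, 0))
  expect_equal(sc$time_fraction, c(0.25, 0.5, 0.25))
  expect_equal(sum(sc$time_fraction), 1)
  # absent state flagged missing, fraction 1 for a single-state recording
  b1 <- structure(data.frame(state = "QS", start_frame = 0L,
                             end_frame = 400L),
                  states = rep("QS", 400),
                  class = c("sleep_bouts", "data.frame"))
  sc1 <- state_conditioned_signal(rnorm(400), b1)
  expect_true(is.na(sc1$mean_signal[sc1$state == "wake"]))
  expect_equal(sc1$time_fraction[sc1$state == "QS"], 1)
})
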