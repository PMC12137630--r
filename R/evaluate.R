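# Study-level evaluation runs: each function simulates data at a stated
# problem size, runs the corresponding analysis, and reports recovery or
# calibration statistics. The analysis drivers, the test suite and the
# acceptance script all call these, so the numbers they report are always
# recomputed from scratch.

#' Event-detector agreement with the brute-force reference
#'
#' Generates random small recordings (noise plus a handful of planted
#' multi-cell transients), runs [detect_events()] and
#' [detect_events_naive()] on each, and reports the fraction of
#' recordings on which the two agree exactly on peak frames, intervals,
#' participation and class.
#'
#' @param n_recordings number of random recordings.
#' @param max_cells,max_frames upper bounds of the random sizes.
#' @param seed RNG seed.
#' @return list: `agreement` (fraction of recordings in full agreement),
#'   `n`.
#' @export
evaluate_event_oracle <- function(n_recordings = 100L, max_cells = 20L,
                                  max_frames = 3000L, seed = 1L) {
  agree <- with_seed(substream_seed(seed, "oracle"), {
    vapply(seq_len(n_recordings), function(i) {
      nc <- sample(2:max_cells, 1)
      nt <- sample(300:max_frames, 1)
      raw <- matrix(abs(stats::rnorm(nc * nt, 100, 15)) + 1, nc, nt)
      for (k in seq_len(sample(0:6, 1))) {
        f <- sample(nt - 90, 1)
        dur <- sample(10:60, 1)
        cells <- sample(nc, sample(nc, 1))
        raw[cells, f:(f + dur)] <- raw[cells, f:(f + dur)] *
          stats::runif(1, 1.2, 2.5)
      }
      dff <- dff_percentile(fluorescence_recording(raw))
      a <- as.data.frame(detect_events(dff))
      b <- as.data.frame(detect_events_naive(dff))
      isTRUE(all.equal(a, b, check.attributes = FALSE))
    }, TRUE)
  })
  list(agreement = mean(agree), n = n_recordings)
}

#' Recovery of planted population events
#'
#' Simulates baseline recordings at the study scale (default 50
#' recordings of 200 cells, 10 min at 30 Hz, default noise), detects
#' events on the first-percentile dF/F, matches them to the planted
#' ground truth (0.5 s peak tolerance) and reports detection rate, mean
#' participation error (percentage points), H/L class confusion among
#' detected events, and false events as a fraction of planted ones.
#'
#' @param n_recordings number of simulated recordings.
#' @param n_cells,duration_s recording size per simulation.
#' @param seed RNG seed.
#' @return list: `detection_rate`, `participation_error_points`,
#'   `class_confusion`, `false_event_fraction`, `n`.
#' @export
evaluate_event_recovery <- function(n_recordings = 50L, n_cells = 200L,
                                    duration_s = 600, seed = 1L) {
  per <- lapply(seq_len(n_recordings), function(i) {
    sim <- simulate_recording(sim_config(n_cells = n_cells,
                                         duration_s = duration_s,
                                         seed = seed * 1000L + i))
    dff <- dff_percentile(sim$recording)
    ev <- detect_events(dff)
    mt <- match_events(ev, sim$truth$events,
                       frame_rate = sim$recording$frame_rate)
    hl <- mt$detected & mt$class %in% c("H", "L")
    data.frame(
      planted = nrow(mt), detected = sum(mt$detected),
      false = nrow(ev) - sum(mt$detected),
      perr = mean(abs(mt$participation_detected -
                        mt$participation)[mt$detected]) * 100,
      confused = sum(hl & mt$class_detected != mt$class &
                       mt$class_detected %in% c("H", "L")),
      n_hl = sum(hl))
  })
  d <- do.call(rbind, per)
  list(detection_rate = sum(d$detected) / sum(d$planted),
       participation_error_points = mean(d$perr),
       class_confusion = sum(d$confused) / sum(d$n_hl),
       false_event_fraction = sum(d$false) / sum(d$planted),
       n = n_recordings)
}

# a stimulus battery at the experimental cadence: n trials, 20-30 s ISI
stimulus_battery <- function(n_trials = 10L, type = "airpuff",
                             frame_rate = 30, seed = 1L) {
  onsets <- with_seed(substream_seed(seed, "battery"),
                      round(cumsum(stats::runif(n_trials, 20, 30)) *
                              frame_rate))
  stimulus_log(onsets, rep(type, n_trials))
}

#' Calibration and power of the responsiveness test
#'
#' Null side: simulates recordings with stimuli of zero amplitude
#' (default 200 recordings, 100 cells, 10 trials) and reports the
#' empirical false discovery rate of the Shapiro-gated paired-test +
#' Benjamini-Hochberg pipeline (mean of V / max(R, 1); every discovery on
#' null data is false). Power side: plants responders in half the cells
#' with a response calibrated to `effect_x` times the null SD of the
#' per-trial paired differences, and reports sensitivity.
#'
#' @param n_null null recordings.
#' @param n_power recordings with planted responders.
#' @param n_cells,n_trials per-recording size.
#' @param effect_x planted effect size in null-SD units.
#' @param alpha test level.
#' @param seed RNG seed.
#' @return list: `empirical_fdr`, `sensitivity`, `n_null`, `n_power`.
#' @export
evaluate_responsiveness <- function(n_null = 200L, n_power = 10L,
                                    n_cells = 100L, n_trials = 10L,
                                    effect_x = 3, alpha = 0.05,
                                    seed = 1L) {
  fs <- 30
  run_one <- function(s, amplitude, responder_fraction) {
    sl <- stimulus_battery(n_trials, seed = s)
    dur <- max(sl$onset_frame) / fs + 25
    cfg <- sim_config(
      n_cells = n_cells, duration_s = dur, event_rate_per_min = 0,
      seed = s,
      stim_schedule = list(log = sl,
                           amplitude = list(airpuff = amplitude),
                           responder_fraction =
                             list(airpuff = responder_fraction)))
    sim <- simulate_recording(cfg)
    dff <- dff_percentile(sim$recording)
    list(rt = responsiveness_test(dff, sl, alpha = alpha), sim = sim,
         dff = dff, sl = sl)
  }

  # calibrate the planted amplitude: unit-amplitude mean paired shift and
  # the null SD of per-trial paired differences
  paired_diffs <- function(dff, sl) {
    pre <- vapply(sl$onset_frame, function(on)
      rowMeans(dff$dff[, (on - fs + 1):on]), numeric(nrow(dff$dff)))
    post <- vapply(sl$onset_frame, function(on)
      rowMeans(dff$dff[, (on + 1):(on + fs)]), numeric(nrow(dff$dff)))
    post - pre
  }
  cal <- run_one(substream_seed(seed, "calibrate"), 1, 1)
  d1 <- mean(paired_diffs(cal$dff, cal$sl))
  nul <- run_one(substream_seed(seed, "nullsd"), 0, 0)
  sd0 <- stats::sd(paired_diffs(nul$dff, nul$sl))
  amplitude <- effect_x * sd0 / d1

  fdr <- vapply(seq_len(n_null), function(i) {
    rt <- run_one(seed * 2000L + i, 0, 0)$rt
    sum(rt$responsive) / max(1L, sum(rt$responsive)) *
      (sum(rt$responsive) > 0)
  }, 0)

  sens <- vapply(seq_len(n_power), function(i) {
    r <- run_one(seed * 3000L + i, amplitude, 0.5)
    resp0 <- r$sim$truth$responders$airpuff - 1L
    mean(r$rt$responsive[r$rt$cell %in% resp0])
  }, 0)

  list(empirical_fdr = mean(fdr), sensitivity = mean(sens),
       n_null = n_null, n_power = n_power)
}

#' Calibration of the permutation-thresholded decoder
#'
#' Simulates global-null condition experiments (default 8 animals, 2
#' conditions, 10 trials each) and reports the fraction whose
#' max-over-bins accuracy exceeds the permutation threshold — which
#' should match the nominal `alpha`. With a planted condition effect, it
#' reports the fraction of seeds with a positive
#' accuracy-minus-threshold margin.
#'
#' @param n_experiments null replicate experiments.
#' @param n_effect_seeds replicate experiments with the planted effect.
#' @param effect planted effect size (trial-noise SD units).
#' @param n_perm permutations per experiment.
#' @param n_cells cells (feature dimension) per experiment.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list: `null_rejection_rate`, `positive_margin_rate`,
#'   `n_experiments`.
#' @export
evaluate_decoding_calibration <- function(n_experiments = 200L,
                                          n_effect_seeds = 20L,
                                          effect = 1, n_perm = 500L,
                                          n_cells = 20L, alpha = 0.05,
                                          seed = 1L) {
  rej <- vapply(seq_len(n_experiments), function(r) {
    tt <- simulate_condition_experiment(effect = 0, n_cells = n_cells,
                                        seed = seed * 4000L + r)
    decode_condition(tt, n_cells = n_cells, n_perm = n_perm,
                     alpha = alpha, seed = seed * 4000L + r)$significant
  }, TRUE)
  marg <- vapply(seq_len(n_effect_seeds), function(r) {
    tt <- simulate_condition_experiment(effect = effect,
                                        n_cells = n_cells,
                                        seed = seed * 5000L + r)
    decode_condition(tt, n_cells = n_cells, n_perm = n_perm,
                     alpha = alpha, seed = seed * 5000L + r)$margin
  }, 0)
  list(null_rejection_rate = mean(rej),
       positive_margin_rate = mean(marg > 0),
       n_experiments = n_experiments)
}

#' Recovery of planted sleep states
#'
#' Simulates pose-tracking movement over mixed bout plans (50 seeds by
#' default), scores it with [score_sleep_states()], and reports mean
#' frame-wise accuracy and active-sleep recall against the planted
#' labels.
#'
#' @param n_seeds replicate simulations.
#' @param seed RNG seed.
#' @return list: `frame_accuracy`, `as_recall`, `n`.
#' @export
evaluate_sleep_recovery <- function(n_seeds = 50L, seed = 1L) {
  plans <- list(
    data.frame(state = c("wake", "QS", "AS", "QS", "wake", "AS"),
               duration_s = c(40, 80, 80, 60, 30, 70)),
    data.frame(state = c("QS", "AS", "wake", "QS"),
               duration_s = c(90, 60, 60, 90)),
    data.frame(state = c("AS", "QS", "AS", "wake"),
               duration_s = c(80, 90, 60, 40)))
  per <- vapply(seq_len(n_seeds), function(s) {
    plan <- plans[[(s %% length(plans)) + 1L]]
    cfg <- sim_config(seed = seed * 6000L + s)
    mv <- simulate_movement(cfg, plan)
    move <- movement_from_pose(mv$pose)
    st <- attr(score_sleep_states(move), "states")
    truth <- mv$truth$states[-length(mv$truth$states)]
    c(acc = mean(st == truth),
      rec = mean(st[truth == "AS"] == "AS"))
  }, c(acc = 0, rec = 0))
  list(frame_accuracy = mean(per["acc", ]),
       as_recall = mean(per["rec", ]), n = n_seeds)
}

#' Recovery of planted postsynaptic currents
#'
#' Plants double-exponential PSCs (0.5 ms rise, 5 ms decay) at known
#' onset latencies in noisy sweeps at signal-to-noise ratios from 5 to
#' 15, extracts features with [extract_psc_features()], and reports mean
#' absolute onset error (ms) and mean relative charge error (%).
#'
#' @param n_sweeps planted sweeps.
#' @param snr_range SNR values cycled across sweeps.
#' @param seed RNG seed.
#' @return list: `onset_error_ms`, `charge_error_pct`, `failure_rate`,
#'   `n`.
#' @export
evaluate_psc_recovery <- function(n_sweeps = 40L,
                                  snr_range = c(5, 8, 10, 15),
                                  seed = 1L) {
  fs <- 20000; ms <- fs / 1000
  res <- with_seed(substream_seed(seed, "psc"), {
    t(vapply(seq_len(n_sweeps), function(i) {
      snr <- snr_range[(i %% length(snr_range)) + 1L]
      onset_ms <- stats::runif(1, 2, 30)
      n <- round(0.3 * fs); stim <- round(0.1 * fs)
      tms <- seq(0, 100, by = 1 / ms)
      shape <- exp(-tms / 5) - exp(-tms / 0.5)
      shape <- shape / max(shape)
      noise_sd <- 2
      amp <- snr * noise_sd
      x <- stats::rnorm(n, 0, noise_sd)
      on <- stim + round(onset_ms * ms)
      idx <- on:min(n, on + length(shape) - 1L)
      x[idx] <- x[idx] + amp * shape[seq_along(idx)]
      f <- extract_psc_features(x, stim)
      c(fail = f$is_failure,
        oerr = abs(f$onset_ms - onset_ms),
        cerr = abs(f$charge_pc - amp * sum(shape) / ms / 1000) /
          (amp * sum(shape) / ms / 1000))
    }, c(fail = 0, oerr = 0, cerr = 0)))
  })
  ok <- res[, "fail"] == 0
  list(onset_error_ms = mean(res[ok, "oerr"]),
       charge_error_pct = 100 * mean(res[ok, "cerr"]),
       failure_rate = mean(res[, "fail"]), n = n_sweeps)
}

#' Interneuron-identification mask size on continuous red channels
#'
#' Draws continuous-valued per-cell red fluorescence and checks that the
#' 97th-percentile rule flags ceiling(0.03 n) cells within +/- 1, and
#' that a high-contrast synthetic recording recovers the planted
#' interneuron set exactly.
#'
#' @param n_cells_grid cell counts to test.
#' @param seed RNG seed.
#' @return list: `max_size_deviation` (max abs deviation from
#'   ceiling(0.03 n) over the grid), `ground_truth_recovery` (fraction of
#'   simulations whose mask equals the planted set), `n`.
#' @export
evaluate_interneuron_rule <- function(n_cells_grid = c(34, 50, 100, 150,
                                                       200, 333, 500),
                                      seed = 1L) {
  dev <- with_seed(substream_seed(seed, "mask"), {
    vapply(n_cells_grid, function(n) {
      sizes <- vapply(1:20, function(i) {
        red <- fluorescence_recording(
          matrix(stats::rlnorm(n * 30, log(10), 1), n, 30),
          channel = "red")
        sum(identify_interneurons(red))
      }, 0)
      max(abs(sizes - ceiling(0.03 * n)))
    }, 0)
  })
  rec <- vapply(1:20, function(i) {
    sim <- simulate_recording(sim_config(n_cells = 100, duration_s = 30,
                                         seed = seed * 8000L + i))
    mask <- identify_interneurons(sim$red)
    setequal(which(mask), sim$truth$interneurons)
  }, TRUE)
  list(max_size_deviation = max(dev),
       ground_truth_recovery = mean(rec), n = length(n_cells_grid))
}
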