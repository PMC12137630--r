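#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions the analysis pipeline is built for: 10 min baseline
#' recordings of ~200 layer-2/3 cells at 30 Hz in a 643 um field of view,
#' GCaMP6s-like transients (difference-of-exponentials kernel, 0.18 s
#' rise, 1.6 s decay), spontaneous population events at a few per minute
#' with participation fractions spanning the L- and H-event ranges,
#' distance-dependent shared noise, and a sparse bright red (tdTomato)
#' channel marking interneurons.
#'
#' @param n_cells number of cells.
#' @param duration_s recording length in seconds (default 600 = 10 min).
#' @param frame_rate frames per second.
#' @param fov_um field-of-view width (square), micrometres.
#' @param baseline_f0 list `(mean, sd)` of the per-cell lognormal baseline
#'   fluorescence (a.u.).
#' @param kernel list `(rise_s, decay_s)` of the transient kernel.
#' @param noise_sd per-cell white-noise SD, in fractional (dF/F) units.
#' @param shared_sd SD of the distance-correlated shared noise component.
#' @param spatial_corr_length_um length scale of the shared-noise field.
#' @param event_rate_per_min spontaneous population-event rate used when no
#'   explicit `event_schedule` is given.
#' @param event_amplitude peak dF/F of a planted event in recruited cells.
#' @param event_duration_s range (min, max) of the drive duration in s.
#' @param participation_range range the planted participation fraction is
#'   drawn from (uniform).
#' @param event_schedule optional data.frame `(time_s, duration_s,
#'   participation, amplitude)` overriding the spontaneous schedule.
#' @param stim_schedule optional list: `log` a [stimulus_log()] (onsets in
#'   frames) plus per-type `amplitude` and `responder_fraction` named
#'   vectors.
#' @param red_interneuron_fraction fraction of cells that are interneurons
#'   (bright in the red channel).
#' @param wake_step,jitter_sd,twitch_rate_hz,twitch_amp,twitch_dur_s
#'   movement-generator parameters (displacement units per frame; twitch
#'   rate in Hz during active sleep).
#' @param serotonin_offsets named state offsets of the serotonin-sensor
#'   baseline (wake > QS > AS).
#' @param serotonin_noise_sd,serotonin_stim_amp,serotonin_decay_s
#'   serotonin-trace noise, stimulus-transient amplitude and decay.
#' @param seed master seed; every random draw is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L, duration_s = 600, frame_rate = 30,
                       fov_um = 643,
                       baseline_f0 = list(mean = 300, sd = 60),
                       kernel = list(rise_s = 0.18, decay_s = 1.6),
                       noise_sd = 0.05, shared_sd = 0.02,
                       spatial_corr_length_um = 100,
                       event_rate_per_min = 4,
                       event_amplitude = 0.5,
                       event_duration_s = c(0.5, 2),
                       participation_range = c(0.2, 1.0),
                       event_schedule = NULL,
                       stim_schedule = NULL,
                       red_interneuron_fraction = 0.03,
                       wake_step = 3, jitter_sd = 0.15,
                       twitch_rate_hz = 0.5, twitch_amp = 4,
                       twitch_dur_s = 0.1,
                       serotonin_offsets = c(wake = 1, QS = 0.5, AS = 0),
                       serotonin_noise_sd = 0.05,
                       serotonin_stim_amp = 2, serotonin_decay_s = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_cells >= 1, duration_s > 0, frame_rate > 0,
            kernel$rise_s > 0, kernel$decay_s > kernel$rise_s,
            noise_sd >= 0, shared_sd >= 0,
            red_interneuron_fraction >= 0, red_interneuron_fraction <= 1)
  if (any(participation_range < 0) || any(participation_range > 1))
    stop("participation fractions must lie in [0, 1]")
  if (!is.null(event_schedule)) {
    if (any(event_schedule$participation < 0 | event_schedule$participation > 1))
      stop("participation fractions must lie in [0, 1]")
    if (any(event_schedule$time_s + event_schedule$duration_s > duration_s))
      stop("event schedule extends past recording duration")
  }
  structure(cfg, class = "sim_config")
}

# Impulse response of the transient kernel via two AR(1) recursions,
# normalised so a unit-amplitude drive boxcar peaks at 1 in dF/F.
kernel_response <- function(drive_tc, rise_s, decay_s, frame_rate) {
  ad <- exp(-1 / (frame_rate * decay_s))
  ar <- exp(-1 / (frame_rate * rise_s))
  ed <- stats::filter(drive_tc, ad, method = "recursive")
  er <- stats::filter(drive_tc, ar, method = "recursive")
  matrix(as.numeric(ed - er), nrow = nrow(drive_tc))
}

# Peak (and argmax, frames) of the response to a unit boxcar of d frames.
boxcar_peak <- function(d_frames, rise_s, decay_s, frame_rate, horizon = NULL) {
  horizon <- horizon %||% (d_frames + ceiling(6 * decay_s * frame_rate))
  imp <- matrix(0, horizon, 1)
  imp[seq_len(d_frames), 1] <- 1
  resp <- kernel_response(imp, rise_s, decay_s, frame_rate)
  list(peak = max(resp), argmax = which.max(resp) - 1L)
}

#' Simulate a fluorescence recording with known ground truth
#'
#' Builds traces as
#' `raw = f0 * (1 + drive (x) kernel + shared spatial noise + white noise)`,
#' where the drive contains the planted population events (each recruiting
#' a random subset of cells at the configured participation fraction) and
#' any stimulus-locked responses, and the shared noise is a low-rank
#' Gaussian field with the configured spatial length scale. Three
#' independent RNG substreams (events, placement, noise) are derived from
#' the master seed, so changing `n_cells` does not move event times.
#'
#' @param config a [sim_config()].
#' @return A list with elements `recording` (green-channel
#'   [fluorescence_recording()]), `red` (short red-channel recording for
#'   interneuron identification), and `truth`: planted event table
#'   (`onset_frame`, `peak_frame`, `duration_s`, `participation`,
#'   `amplitude`, `class`), per-event participant index list, true
#'   interneuron indices, and per-stimulus responder index sets.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$frame_rate
  n_t <- round(config$duration_s * fs)
  n_c <- as.integer(config$n_cells)

  # -- placement stream: geometry, per-cell baselines, cell subsets
  pl <- with_seed(substream_seed(config$seed, "placement"), {
    coords <- matrix(stats::runif(2 * n_c, 0, config$fov_um), n_c, 2)
    mu <- config$baseline_f0$mean; sd <- config$baseline_f0$sd
    sl <- sqrt(log(1 + (sd / mu)^2))
    f0 <- stats::rlnorm(n_c, log(mu) - sl^2 / 2, sl)
    n_in <- ceiling(config$red_interneuron_fraction * n_c)
    interneurons <- if (n_in > 0) sort(sample.int(n_c, n_in)) else integer()
    list(coords = coords, f0 = f0, interneurons = interneurons)
  })

  # -- events stream: schedule (times, durations, fractions, amplitudes)
  sched <- config$event_schedule
  if (is.null(sched)) {
    n_ev <- round(config$event_rate_per_min * config$duration_s / 60)
    sched <- with_seed(substream_seed(config$seed, "events"), {
      if (n_ev == 0) {
        data.frame(time_s = numeric(), duration_s = numeric(),
                   participation = numeric(), amplitude = numeric())
      } else {
        # jittered regular grid keeps events well separated
        grid <- (seq_len(n_ev) - 0.5) * config$duration_s / n_ev
        jit <- stats::runif(n_ev, -0.15, 0.15) * config$duration_s / n_ev
        data.frame(
          time_s = grid + jit,
          duration_s = stats::runif(n_ev, config$event_duration_s[1],
                                    config$event_duration_s[2]),
          participation = stats::runif(n_ev, config$participation_range[1],
                                       config$participation_range[2]),
          amplitude = config$event_amplitude *
            stats::runif(n_ev, 0.8, 1.2))
      }
    })
  }
  if (nrow(sched) && any(sched$time_s + sched$duration_s > config$duration_s))
    stop("event schedule extends past recording duration")

  # -- participants drawn in the placement stream (depends on n_cells)
  participants <- with_seed(substream_seed(config$seed, "participants"), {
    lapply(seq_len(nrow(sched)), function(i) {
      k <- round(sched$participation[i] * n_c)
      if (k == 0) integer() else sort(sample.int(n_c, k))
    })
  })

  # -- drive matrix (frames x cells), boxcars scaled to peak at `amplitude`
  drive <- matrix(0, n_t, n_c)
  peak_frame <- integer(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    on <- round(sched$time_s[i] * fs)
    d <- max(1L, round(sched$duration_s[i] * fs))
    bp <- boxcar_peak(d, config$kernel$rise_s, config$kernel$decay_s, fs)
    idx <- (on + 1L):min(on + d, n_t)
    drive[idx, participants[[i]]] <- drive[idx, participants[[i]]] +
      sched$amplitude[i] / bp$peak
    peak_frame[i] <- on + bp$argmax
  }

  # -- stimulus-locked responses
  responders <- list()
  if (!is.null(config$stim_schedule)) {
    ss <- config$stim_schedule
    types <- unique(ss$log$stimulus_type)
    responders <- with_seed(substream_seed(config$seed, "responders"), {
      stats::setNames(lapply(types, function(ty) {
        fr <- ss$responder_fraction[[ty]] %||% 0
        k <- round(fr * n_c)
        if (k == 0) integer() else sort(sample.int(n_c, k))
      }), types)
    })
    for (j in seq_len(nrow(ss$log))) {
      ty <- ss$log$stimulus_type[j]
      amp <- ss$amplitude[[ty]] %||% 0
      cells <- responders[[ty]]
      if (amp == 0 || !length(cells)) next
      on <- ss$log$onset_frame[j]
      d <- max(1L, round(0.2 * fs))
      bp <- boxcar_peak(d, config$kernel$rise_s, config$kernel$decay_s, fs)
      idx <- (on + 1L):min(on + d, n_t)
      drive[idx, cells] <- drive[idx, cells] + amp / bp$peak
    }
  }

  dff_clean <- kernel_response(drive, config$kernel$rise_s,
                               config$kernel$decay_s, fs)

  # -- noise stream: shared low-rank spatial field + white noise
  noise <- with_seed(substream_seed(config$seed, "noise"), {
    out <- matrix(stats::rnorm(n_t * n_c, 0, config$noise_sd), n_t, n_c)
    if (config$shared_sd > 0 && is.finite(config$spatial_corr_length_um)) {
      K <- 25L
      centers <- matrix(stats::runif(2 * K, 0, config$fov_um), K, 2)
      d2 <- outer(pl$coords[, 1], centers[, 1], "-")^2 +
            outer(pl$coords[, 2], centers[, 2], "-")^2
      L <- exp(-d2 / (2 * config$spatial_corr_length_um^2))   # n_c x K
      # slow latent factors: AR(1) with ~0.5 s time constant
      a <- exp(-1 / (fs * 0.5))
      z <- apply(matrix(stats::rnorm(n_t * K), n_t, K), 2,
                 function(v) as.numeric(stats::filter(v, a, "recursive")))
      z <- z * sqrt(1 - a^2)                                   # unit variance
      shared <- z %*% t(L)                                     # n_t x n_c
      cell_sd <- sqrt(rowSums(L^2))
      cell_sd[cell_sd == 0] <- 1
      out <- out + config$shared_sd * sweep(shared, 2, cell_sd, "/")
    }
    out
  })

  raw <- t((1 + dff_clean + noise) * rep(pl$f0, each = n_t))
  raw[raw <= 0] <- 1e-3   # fluorescence is nonnegative

  rec <- fluorescence_recording(raw, pl$coords, fs, "green",
                                metadata = list(source = "synthetic"))

  # -- red channel: 20 s, interneurons bright, others dim (continuous)
  red <- with_seed(substream_seed(config$seed, "red"), {
    n_rt <- round(20 * fs)
    base <- stats::rlnorm(n_c, log(5), 0.5)
    base[pl$interneurons] <- stats::rlnorm(length(pl$interneurons),
                                           log(120), 0.3)
    rr <- matrix(stats::rnorm(n_c * n_rt, 0, 0.5), n_c, n_rt) + base
    rr[rr <= 0] <- 1e-3
    fluorescence_recording(rr, pl$coords, fs, "red")
  })

  h_thr <- 0.80; l_thr <- 0.20
  planted_frac <- if (nrow(sched)) {
    vapply(participants, length, 1L) / n_c
  } else numeric()
  truth_events <- data.frame(
    onset_frame = if (nrow(sched)) round(sched$time_s * fs) else integer(),
    peak_frame = peak_frame,
    duration_s = sched$duration_s,
    participation = planted_frac,
    amplitude = sched$amplitude,
    class = if (nrow(sched)) classify_event(planted_frac,
                                            h_thr, l_thr) else character(),
    stringsAsFactors = FALSE)

  list(recording = rec, red = red,
       truth = list(events = truth_events, participants = participants,
                    interneurons = pl$interneurons,
                    responders = responders, f0 = pl$f0))
}

#' Simulate pose-tracking movement with known sleep states
#'
#' Generates marker coordinate time series following a bout plan over the
#' three neonatal states: wake (sustained suprathreshold locomotion),
#' quiet sleep (subthreshold tracking jitter) and active sleep (jitter
#' punctuated by brief isolated myoclonic twitches at
#' `config$twitch_rate_hz`).
#'
#' @param config a [sim_config()].
#' @param bout_plan data.frame `(state, duration_s)` with states in
#'   `wake`, `QS`, `AS`.
#' @param markers marker names to emit (all share the planted states; only
#'   the scored marker matters downstream).
#' @return list with `pose`: data.frame `(frame, marker, x, y,
#'   likelihood)`, and `truth`: per-frame state labels and twitch onset
#'   frames.
#' @export
simulate_movement <- function(config, bout_plan,
                              markers = "left_forelimb") {
  stopifnot(all(bout_plan$state %in% c("wake", "QS", "AS")))
  fs <- config$frame_rate
  n_per <- round(bout_plan$duration_s * fs)
  states <- rep(bout_plan$state, n_per)
  n_t <- length(states)

  sim <- with_seed(substream_seed(config$seed, "movement"), {
    out <- vector("list", length(markers))
    twitch_frames <- integer()
    for (mi in seq_along(markers)) {
      step <- abs(stats::rnorm(n_t, 0, config$jitter_sd))
      wake_idx <- which(states == "wake")
      step[wake_idx] <- config$wake_step * stats::runif(length(wake_idx),
                                                        0.7, 1.3)
      as_idx <- which(states == "AS")
      if (length(as_idx)) {
        # Poisson twitches, realised as short high-displacement bursts
        p_tw <- config$twitch_rate_hz / fs
        tw_on <- as_idx[stats::runif(length(as_idx)) < p_tw]
        dur <- max(1L, round(config$twitch_dur_s * fs))
        for (f in tw_on) {
          idx <- f:min(f + dur - 1L, n_t)
          idx <- idx[states[idx] == "AS"]
          step[idx] <- pmax(step[idx], config$twitch_amp *
                              stats::runif(length(idx), 0.8, 1.2))
        }
        if (mi == 1L) twitch_frames <- tw_on
      }
      theta <- stats::runif(n_t, 0, 2 * pi)
      x <- cumsum(c(100, (step * cos(theta))[-n_t]))
      y <- cumsum(c(100, (step * sin(theta))[-n_t]))
      out[[mi]] <- data.frame(frame = seq_len(n_t) - 1L,
                              marker = markers[mi], x = x, y = y,
                              likelihood = 1.0)
    }
    list(pose = do.call(rbind, out), twitch_frames = twitch_frames)
  })
  list(pose = sim$pose,
       truth = list(states = states, twitch_frames = sim$twitch_frames))
}

#' Simulate a serotonin-sensor trace
#'
#' Single-ROI sensor trace whose baseline depends on the behavioural state
#' (wake > quiet sleep > active sleep by the configured offsets) and which
#' responds to each stimulus with an exponentially decaying transient.
#'
#' @param config a [sim_config()].
#' @param state_series per-frame state labels (`wake`/`QS`/`AS`).
#' @param stim_log a [stimulus_log()] (may be empty).
#' @return numeric trace of `length(state_series)`.
#' @export
simulate_serotonin <- function(config, state_series, stim_log = stimulus_log()) {
  fs <- config$frame_rate
  n_t <- length(state_series)
  base <- unname(config$serotonin_offsets[state_series])
  if (anyNA(base)) stop("state_series contains labels outside wake/QS/AS")
  drive <- numeric(n_t)
  if (nrow(stim_log) && config$serotonin_stim_amp != 0)
    drive[stim_log$onset_frame + 1L] <- config$serotonin_stim_amp
  trans <- as.numeric(stats::filter(drive,
                                    exp(-1 / (fs * config$serotonin_decay_s)),
                                    method = "recursive"))
  noise <- if (config$serotonin_noise_sd > 0) {
    with_seed(substream_seed(config$seed, "serotonin"),
              stats::rnorm(n_t, 0, config$serotonin_noise_sd))
  } else numeric(n_t)
  base + trans + noise
}

#' Simulate an LSPS input map
#'
#' Builds an 11 x 17 (by default) grid of evoked synaptic charge with
#' planted inputs at known positions, optional additive noise, and the
#' layer geometry attached.
#'
#' @param layer_rows named list mapping layer label to an integer vector of
#'   0-based row indices (pia to white matter).
#' @param planted_inputs data.frame `(row, col, charge)` with 0-based grid
#'   positions.
#' @param n_rows,n_cols grid dimensions.
#' @param noise_sd additive half-normal noise SD (charges stay >= 0).
#' @param soma_position optional `(row, col)`.
#' @param seed RNG seed for the noise.
#' @return An [lsps_map()] with the planted ground truth in
#'   `attr(, "truth")`.
#' @export
simulate_lsps_map <- function(layer_rows, planted_inputs = NULL,
                              n_rows = 11L, n_cols = 17L, noise_sd = 0,
                              soma_position = NULL, seed = 1L) {
  grid <- matrix(0, n_rows, n_cols)
  if (!is.null(planted_inputs) && nrow(planted_inputs)) {
    if (any(planted_inputs$row < 0 | planted_inputs$row >= n_rows |
            planted_inputs$col < 0 | planted_inputs$col >= n_cols))
      stop("planted input outside the ", n_rows, " x ", n_cols, " grid")
    for (i in seq_len(nrow(planted_inputs)))
      grid[planted_inputs$row[i] + 1L, planted_inputs$col[i] + 1L] <-
        grid[planted_inputs$row[i] + 1L, planted_inputs$col[i] + 1L] +
        planted_inputs$charge[i]
  }
  if (noise_sd > 0)
    grid <- grid + with_seed(seed,
      matrix(abs(stats::rnorm(n_rows * n_cols, 0, noise_sd)), n_rows, n_cols))
  m <- lsps_map(grid, layer_rows, soma_position = soma_position)
  attr(m, "truth") <- planted_inputs
  m
}
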