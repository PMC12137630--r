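#' Movement from pose-tracking coordinates
#'
#' Converts per-frame marker coordinates (DeepLabCut-style table:
#' `frame, marker, x, y[, likelihood]`) into per-frame displacement: the
#' Euclidean distance between the 2-D coordinates of consecutive frames,
#' per marker. Points below the likelihood threshold are linearly
#' interpolated across gaps up to `max_interp_gap_s`; longer gaps are
#' left NA (unscorable) and reported.
#'
#' @param pose data.frame with columns `frame`, `marker`, `x`, `y` and
#'   optionally `likelihood`.
#' @param frame_rate frames per second.
#' @param min_likelihood tracking-confidence threshold.
#' @param max_interp_gap_s longest gap bridged by interpolation, seconds.
#' @return list of class `movement_trace`: `displacement` (matrix,
#'   (n_frames - 1) x markers), `frame_rate`.
#' @export
movement_from_pose <- function(pose, frame_rate = 30,
                               min_likelihood = 0.6,
                               max_interp_gap_s = 0.5) {
  stopifnot(all(c("frame", "marker", "x", "y") %in% names(pose)))
  markers <- unique(pose$marker)
  frames <- sort(unique(pose$frame))
  n_t <- length(frames)
  if (n_t < 2L) stop("need >= 2 frames of pose data")
  disp <- matrix(NA_real_, n_t - 1L, length(markers),
                 dimnames = list(NULL, markers))
  max_gap <- round(max_interp_gap_s * frame_rate)
  for (mk in markers) {
    sub <- pose[pose$marker == mk, ]
    sub <- sub[order(sub$frame), ]
    x <- sub$x; y <- sub$y
    if (!is.null(sub$likelihood)) {
      bad <- sub$likelihood < min_likelihood
      x[bad] <- NA; y[bad] <- NA
    }
    x <- interp_short_gaps(x, max_gap)
    y <- interp_short_gaps(y, max_gap)
    n_na <- sum(is.na(x))
    if (n_na > 0)
      message("movement_from_pose: ", n_na, " unscorable frame(s) for ",
              mk, " (gap > ", max_interp_gap_s, " s)")
    disp[, mk] <- sqrt(diff(x)^2 + diff(y)^2)
  }
  structure(list(displacement = disp, frame_rate = frame_rate),
            class = "movement_trace")
}

interp_short_gaps <- function(v, max_gap) {
  na <- is.na(v)
  if (!any(na) || all(na)) return(v)
  r <- rle(na)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  filled <- stats::approx(which(!na), v[!na], xout = seq_along(v),
                          rule = 2)$y
  for (i in which(r$values)) {
    if (r$lengths[i] <= max_gap) v[starts[i]:ends[i]] <-
        filled[starts[i]:ends[i]]
  }
  v
}

#' Score wake / quiet-sleep / active-sleep bouts from movement
#'
#' Implements the qualitative neonatal scoring criteria — continuous
#' movement is wakefulness, lack of movement quiet sleep (QS), and sharp
#' isolated twitches during immobility active sleep (AS) — with explicit
#' quantitative thresholds. The displacement of the scored marker
#' (default the left forelimb, the best-visibility marker) is
#' median-filtered (`median_filter_s`) to suppress tracking jitter, then:
#'
#' * suprathreshold (`>= theta_move`) runs lasting at least `min_wake_s`
#'   are wake;
#' * shorter suprathreshold excursions (`<= max_twitch_s`) inside
#'   immobility are twitches;
#' * sleep frames within `as_halo_s` of a twitch are AS, the rest QS.
#'
#' Bouts tile the scored interval without overlap.
#'
#' @param move a `movement_trace`.
#' @param marker marker column to score.
#' @param theta_move immobility threshold (displacement units/frame).
#' @param median_filter_s median-filter width, seconds.
#' @param min_wake_s minimum duration of a wake bout, seconds.
#' @param max_twitch_s maximum duration of a twitch, seconds.
#' @param as_halo_s AS labelling halo around each twitch, seconds.
#' @return data.frame of class `sleep_bouts`: `state`, `start_frame`,
#'   `end_frame` (half-open); per-frame labels in `attr(, "states")`,
#'   twitch onsets in `attr(, "twitch_frames")`.
#' @export
score_sleep_states <- function(move, marker = "left_forelimb",
                               theta_move = 1.0, median_filter_s = 0.2,
                               min_wake_s = 1.0, max_twitch_s = 0.5,
                               as_halo_s = 2.5) {
  stopifnot(inherits(move, "movement_trace"))
  if (max_twitch_s >= min_wake_s)
    stop("max_twitch_s must be < min_wake_s (twitches are shorter than ",
         "the shortest wake bout)")
  if (!marker %in% colnames(move$displacement))
    stop("no marker '", marker, "' in movement trace; have: ",
         paste(colnames(move$displacement), collapse = ", "))
  fs <- move$frame_rate
  d <- move$displacement[, marker]
  d[is.na(d)] <- 0
  k <- round(median_filter_s * fs)
  if (k %% 2 == 0) k <- k + 1L
  # wake is scored on the median-filtered trace (jitter-robust); twitches
  # on the raw trace, because the filter erases spikes shorter than half
  # its window — which is exactly what a twitch is
  ds <- if (k >= 3 && k <= length(d)) stats::runmed(d, k) else d
  n <- length(ds)
  min_wake_f <- round(min_wake_s * fs)
  max_twitch_f <- round(max_twitch_s * fs)

  states <- rep("QS", n)
  r <- rle(ds >= theta_move)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (r$lengths[i] > max_twitch_f)   # sustained movement: wake
      states[starts[i]:ends[i]] <- "wake"
  }

  twitch_frames <- integer()
  rr <- rle(d >= theta_move)
  rends <- cumsum(rr$lengths); rstarts <- rends - rr$lengths + 1L
  for (i in seq_along(rr$values)) {
    if (!rr$values[i] || rr$lengths[i] > max_twitch_f) next
    if (all(states[rstarts[i]:rends[i]] != "wake"))
      twitch_frames <- c(twitch_frames, rstarts[i])
  }
  halo_f <- round(as_halo_s * fs)
  for (f in twitch_frames) {
    idx <- max(1L, f - halo_f):min(n, f + halo_f)
    states[idx][states[idx] == "QS"] <- "AS"
  }
  rb <- rle(states)
  bend <- cumsum(rb$lengths); bstart <- bend - rb$lengths + 1L
  bouts <- data.frame(state = rb$values, start_frame = bstart - 1L,
                      end_frame = bend, stringsAsFactors = FALSE)
  structure(bouts, states = states, twitch_frames = twitch_frames - 1L,
            params = list(theta_move = theta_move,
                          median_filter_s = median_filter_s,
                          min_wake_s = min_wake_s,
                          max_twitch_s = max_twitch_s,
                          as_halo_s = as_halo_s),
            class = c("sleep_bouts", "data.frame"))
}

#' Condition a signal on behavioural state
#'
#' Per-state mean of a simultaneously recorded 1-D signal (e.g. the
#' serotonin-sensor trace) over the frames of each state, plus the
#' fraction of scored time spent in each state.
#'
#' @param signal numeric trace covering the scored interval.
#' @param bouts a `sleep_bouts` table.
#' @return data.frame: `state`, `mean_signal` (NA when the state is
#'   absent), `time_fraction` (sums to 1 over scored frames).
#' @export
state_conditioned_signal <- function(signal, bouts) {
  states <- attr(bouts, "states")
  if (is.null(states)) {
    states <- character(max(bouts$end_frame))
    for (i in seq_len(nrow(bouts)))
      states[(bouts$start_frame[i] + 1L):bouts$end_frame[i]] <-
        bouts$state[i]
  }
  if (length(signal) < length(states))
    stop("signal (", length(signal), ") shorter than scored interval (",
         length(states), ")")
  signal <- signal[seq_along(states)]
  lv <- c("wake", "QS", "AS")
  data.frame(
    state = lv,
    mean_signal = vapply(lv, function(s)
      if (any(states == s)) mean(signal[states == s]) else NA_real_, 0),
    time_fraction = vapply(lv, function(s) mean(states == s), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
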