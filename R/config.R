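#' Analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults. Defaults
#' follow the acquisition and analysis settings the pipeline was designed
#' around: 30 Hz imaging in a 643 um field of view, 6 s event-detection
#' bins, >80% / 20-80% participation thresholds for H-/L-events, 40 um
#' correlation distance bins, 1 s pre/post responsiveness windows with a
#' 20 s response-amplitude window, 97th-percentile interneuron
#' identification, L2 logistic decoding (penalty 0.001, 500 cells, 500 ms
#' bins, 60/40 subject-wise split, 7000 permutations), and 0-50 ms PSC
#' onset windows at 20 kHz.
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    io = list(
      frame_rate = 30,          # Hz
      fov_um = 643,             # field-of-view width, um
      um_per_px = NA_real_      # filled as fov_um / image width when needed
    ),
    normalization = list(
      method = "percentile",    # "percentile" (development) or "mean" (adult)
      percentile = 1,           # first percentile of raw F per cell
      savgol_window = 31,       # frames (~1 s at 30 Hz)
      savgol_polyorder = 3,
      ratiometric_mode = "subtract",  # or "divide"
      grid = c(16L, 16L)        # 256-subregion grid
    ),
    events = list(
      bin_s = 6,                # detection bin length, s
      min_duration_s = 1,       # discard shorter threshold crossings
      h_threshold = 0.80,       # participation > 0.80 -> H
      l_threshold = 0.20,       # 0.20 <= participation <= 0.80 -> L
      method = "interval",      # "interval" or "binned"
      reference = "recording"   # threshold reference mean
    ),
    metrics = list(
      distance_bin_um = 40,
      response_window_s = 20,   # post-stimulus amplitude window
      pre_s = 1, post_s = 1,    # responsiveness windows
      alpha = 0.05,
      interneuron_percentile = 97
    ),
    sleep = list(
      marker = "left_forelimb",
      theta_move = 1.0,         # displacement units / frame
      median_filter_s = 0.2,
      min_wake_s = 1.0,
      min_still_s = 2.0,
      max_twitch_s = 0.5,
      min_gap_s = 1.0,
      as_halo_s = 2.5,          # sleep frames within this of a twitch -> AS
      max_interp_gap_s = 0.5
    ),
    decoding = list(
      n_cells = 500L,
      bin_ms = 500,
      window_s = 20,
      lambda = 0.001,           # L2 penalty weight on the coefficients
      penalty = "lambda",       # "lambda" (penalty weight) or "C" (inverse)
      split = c(0.6, 0.4),
      n_perm = 7000L,
      alpha = 0.05,
      tol = 1e-6,
      max_iter = 5000L
    ),
    lsps = list(
      n_rows = 11L, n_cols = 17L,
      row_spacing_um = 50
    ),
    psc = list(
      sample_rate = 20000,      # Hz
      window_ms = c(0, 50),
      onset_k_sd = 3,           # onset threshold, baseline SDs
      onset_sustain_ms = 0.5,
      smooth_ms = 0.5,          # boxcar width for onset/return detection
      return_k_sd = 1,
      max_integration_ms = 200
    ),
    seed = 1L
  )
}

config_ranges <- list(
  "normalization.percentile"  = c(0, 50),
  "normalization.savgol_window" = c(3, Inf),
  "events.bin_s"              = c(0.1, Inf),
  "events.h_threshold"        = c(0, 1),
  "events.l_threshold"        = c(0, 1),
  "metrics.distance_bin_um"   = c(1, Inf),
  "metrics.alpha"             = c(0, 1),
  "metrics.interneuron_percentile" = c(50, 100),
  "sleep.theta_move"          = c(0, Inf),
  "sleep.min_wake_s"          = c(0, Inf),
  "sleep.max_twitch_s"        = c(0, Inf),
  "decoding.lambda"           = c(0, Inf),
  "decoding.alpha"            = c(0, 1),
  "decoding.n_perm"           = c(1, Inf),
  "psc.onset_k_sd"            = c(0, Inf)
)

#' @rdname default_config
#' @param config nested list to validate (as from [read_config()]).
#' @export
validate_config <- function(config) {
  for (key in names(config_ranges)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    val <- config[[parts[1L]]][[parts[2L]]]
    if (is.null(val)) next
    rng <- config_ranges[[key]]
    if (!is.numeric(val) || any(val < rng[1L] | val > rng[2L]))
      stop("config parameter ", key, " = ", paste(val, collapse = ","),
           " outside allowed range [", rng[1L], ", ", rng[2L], "]")
  }
  if (config$events$l_threshold > config$events$h_threshold)
    stop("config: events.l_threshold must be <= events.h_threshold")
  if (config$sleep$max_twitch_s >= config$sleep$min_wake_s)
    stop("config: sleep.max_twitch_s must be < sleep.min_wake_s ",
         "(a twitch must be shorter than the shortest wake bout)")
  if (abs(sum(config$decoding$split) - 1) > 1e-9)
    stop("config: decoding.split fractions must sum to 1")
  invisible(config)
}

#' @rdname default_config
#' @param path YAML file whose entries override the defaults.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    config <- modify_list_deep(config, user)
  }
  validate_config(config)
  config
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
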