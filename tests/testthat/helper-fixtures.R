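# Shared fixture builders. Everything is generated in code; no files.

# small recording with known content
toy_recording <- function(n_cells = 3, n_frames = 10, value = 100) {
  fluorescence_recording(matrix(value, n_cells, n_frames),
                         coords = cbind(seq_len(n_cells) * 10, 0))
}

# dff_recording wrapper around a plain matrix
as_dff <- function(m, frame_rate = 30) {
  structure(list(dff = m, coords = cbind(seq_len(nrow(m)), 0),
                 frame_rate = frame_rate,
                 provenance = list(method = "fixture")),
            class = "dff_recording")
}

# recording with one boxcar population transient on a flat baseline
boxcar_recording <- function(n_cells = 10, n_frames = 600,
                             onset = 300, dur = 60,
                             cells = seq_len(n_cells), height = 2,
                             baseline = 100) {
  raw <- matrix(baseline, n_cells, n_frames)
  raw[cells, onset:(onset + dur - 1L)] <- baseline * height
  fluorescence_recording(raw)
}

# voltage-clamp sweep with a planted double-exponential PSC
psc_sweep <- function(snr = 10, onset_ms = 5, noise_sd = 2,
                      rise_ms = 0.5, decay_ms = 5, fs = 20000,
                      seed = 1) {
  ms <- fs / 1000
  n <- round(0.3 * fs); stim <- round(0.1 * fs)
  t <- seq(0, 100, by = 1 / ms)
  shape <- exp(-t / decay_ms) - exp(-t / rise_ms)
  shape <- shape / max(shape)
  amp <- snr * noise_sd
  set.seed(seed)
  x <- rnorm(n, 0, noise_sd)
  on <- stim + round(onset_ms * ms)
  idx <- on:min(n, on + length(shape) - 1L)
  x[idx] <- x[idx] + amp * shape[seq_along(idx)]
  list(sweep = x, stim = stim, true_onset_ms = onset_ms, true_amp = amp,
       true_charge_pc = amp * sum(shape) / ms / 1000)
}

# standard 11x17 layer geometry used across LSPS tests
toy_layers <- function() {
  list(L1 = 0L, `L2/3` = 1:3, L4 = 4:5, L5a = 6L, L5b = 7:8, L6 = 9:10)
}
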