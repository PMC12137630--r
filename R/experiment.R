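#' Simulate a multi-animal condition-decoding experiment
#'
#' Generates a [trial_tensor()] for one stimulus type across animals of
#' two (or more) conditions, at the level the decoder consumes:
#' post-stimulus snippets whose per-cell, per-bin means are Gaussian with
#' a per-animal random offset (shared by all trials of an animal, which
#' is what makes subject-wise splitting and animal-level permutation the
#' appropriate analyses) plus, for non-null experiments, a condition
#' effect of size `effect` added to the first half of the cells in every
#' bin.
#'
#' @param n_animals number of animals, split evenly across `conditions`.
#' @param conditions condition labels.
#' @param trials_per_animal trials per animal.
#' @param n_cells cells per snippet.
#' @param n_bins number of feature time bins in the snippet.
#' @param bin_frames frames per bin.
#' @param effect condition effect size, in units of the trial noise SD.
#' @param animal_sd SD of the per-animal offset.
#' @param noise_sd per-bin trial noise SD.
#' @param frame_noise_sd extra white noise per frame.
#' @param frame_rate frames per second.
#' @param stimulus_type stimulus label attached to every trial.
#' @param seed RNG seed.
#' @return a [trial_tensor()].
#' @export
simulate_condition_experiment <- function(n_animals = 8L,
                                          conditions = c("control",
                                                         "treated"),
                                          trials_per_animal = 10L,
                                          n_cells = 20L, n_bins = 8L,
                                          bin_frames = 15L, effect = 0,
                                          animal_sd = 0.1, noise_sd = 1,
                                          frame_noise_sd = 0.2,
                                          frame_rate = 30,
                                          stimulus_type = "airpuff",
                                          seed = 1L) {
  stopifnot(n_animals %% length(conditions) == 0L)
  animals <- paste0("animal", seq_len(n_animals))
  amap <- rep(conditions, each = n_animals / length(conditions))
  n_trials <- n_animals * trials_per_animal
  n_frames <- n_bins * bin_frames
  labels <- data.frame(
    animal = rep(animals, each = trials_per_animal),
    condition = rep(amap, each = trials_per_animal),
    stimulus_type = stimulus_type,
    recording = "r1", stringsAsFactors = FALSE)
  affected <- seq_len(max(1L, n_cells %/% 2L))
  snips <- with_seed(substream_seed(seed, "condition_experiment"), {
    offsets <- matrix(stats::rnorm(n_animals * n_cells, 0, animal_sd),
                      n_animals, n_cells)
    arr <- array(0, c(n_trials, n_cells, n_frames))
    for (tr in seq_len(n_trials)) {
      a <- match(labels$animal[tr], animals)
      binmean <- matrix(stats::rnorm(n_cells * n_bins, 0, noise_sd),
                        n_cells, n_bins) + offsets[a, ]
      if (labels$condition[tr] == conditions[2L] && effect != 0)
        binmean[affected, ] <- binmean[affected, ] + effect * noise_sd
      arr[tr, , ] <- binmean[, rep(seq_len(n_bins), each = bin_frames)] +
        stats::rnorm(n_cells * n_frames, 0, frame_noise_sd)
    }
    arr
  })
  trial_tensor(snips, labels, frame_rate)
}

#' Simulate a single-animal stimulus-type experiment
#'
#' Generates a [trial_tensor()] for the per-animal stimulus-identity
#' decoder: several recordings, each presenting every stimulus type,
#' where each type drives its own random spatiotemporal response pattern
#' (shared across trials of that type) of size `effect` on top of trial
#' noise.
#'
#' @param stimulus_types labels to decode.
#' @param n_recordings recordings (cross-validation folds).
#' @param trials_per_type trials of each type per recording.
#' @param n_cells,n_frames snippet dimensions.
#' @param effect pattern amplitude in trial-noise SD units.
#' @param noise_sd trial noise SD.
#' @param frame_rate frames per second.
#' @param seed RNG seed.
#' @return a [trial_tensor()].
#' @export
simulate_stimulus_experiment <- function(stimulus_types = c("single_whisker",
                                                            "multi_whisker",
                                                            "airpuff"),
                                         n_recordings = 3L,
                                         trials_per_type = 4L,
                                         n_cells = 20L, n_frames = 60L,
                                         effect = 2, noise_sd = 1,
                                         frame_rate = 30, seed = 1L) {
  n_types <- length(stimulus_types)
  n_trials <- n_recordings * n_types * trials_per_type
  labels <- data.frame(
    animal = "animal1", condition = "control",
    stimulus_type = rep(rep(stimulus_types, each = trials_per_type),
                        n_recordings),
    recording = rep(paste0("rec", seq_len(n_recordings)),
                    each = n_types * trials_per_type),
    stringsAsFactors = FALSE)
  snips <- with_seed(substream_seed(seed, "stimulus_experiment"), {
    patterns <- lapply(stimulus_types, function(ty)
      matrix(stats::rnorm(n_cells * n_frames, 0, 1), n_cells, n_frames))
    names(patterns) <- stimulus_types
    arr <- array(stats::rnorm(n_trials * n_cells * n_frames, 0, noise_sd),
                 c(n_trials, n_cells, n_frames))
    for (tr in seq_len(n_trials))
      arr[tr, , ] <- arr[tr, , ] +
        effect * noise_sd * patterns[[labels$stimulus_type[tr]]]
    arr
  })
  trial_tensor(snips, labels, frame_rate)
}
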