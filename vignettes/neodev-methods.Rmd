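---
title: "Methods: population events, sleep states, decoding and input maps in developing cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population events, sleep states, decoding and input maps in developing cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neodev)
```

## Scope and data model

`neodev` implements the analysis chain for developmental two-photon
imaging of neonatal mouse barrel cortex: fluorescence normalisation,
detection and classification of spontaneous population calcium events,
correlation and stimulus-response statistics, sleep-state scoring from
pose tracking, permutation-calibrated population decoding, and ex vivo
input-map (LSPS) analysis. Image registration, ROI segmentation and
trace extraction are upstream of this package (suite2p or equivalent);
the entry point is a cells × frames trace matrix with ROI centroids
(`fluorescence_recording()`), recorded at 30 Hz in a 643 µm field of
view by default. Frames are 0-based and every window is half-open
`[start, end)`; that single convention removes a whole class of
off-by-one ambiguities between modules.

Because the recordings this pipeline was designed for are not publicly
deposited, the package carries a first-class synthetic-data generator
(`simulate_recording()` and friends) whose defaults encode the intended
recording conditions. Every claim the test-suite makes about recovery or
calibration is made against this generator's ground truth.

## Normalisation

Two ΔF/F conventions coexist deliberately:

* `dff_mean_baseline()`: `(F − F̄)/F̄` with `F̄` the mean over a baseline
  window (default the whole session). Used for sensor traces and adult
  recordings.
* `dff_percentile()`: `(F − F₁)/F₁` with `F₁` the per-cell first
  percentile over the whole recording. Calcium physiology changes
  rapidly over the second postnatal week, and a low-percentile baseline
  is far more stable across age than the mean; it is the default for
  developmental data.

Percentiles interpolate linearly between order statistics
(`stats::quantile` type 7, the same convention as NumPy's default); the
choice is recorded in the result's provenance because at 36,000 frames
the difference between conventions is tiny but nonzero. Both variants
are invariant under positive rescaling of raw fluorescence and map
constant traces to zero — properties the test-suite asserts over
randomised inputs, as they catch silent offset bugs.

Sensor traces are smoothed with a Savitzky–Golay filter (3rd-order
polynomial, 31-frame ≈ 1 s windows). Edges are mirror-padded: the
alternatives (polynomial edge fits, truncation) create visible
boundary transients on short traces. Ratiometric correction against the
red structural channel defaults to subtracting the control channel's
ΔF/F — the hemodynamic artefact is a fractional occlusion affecting both
channels — with a raw-ratio division mode (`mode = "divide"`) exposed
because both forms are in circulation; on an artefact-free trace the two
agree to first order.

## Population events (H-/L-events)

Spontaneous synchrony events are defined on the population mean ΔF/F
trace: an event is a maximal contiguous interval on which the population
mean exceeds its recording-wide mean, with peak at the interval's
argmax, amplitude the population ΔF/F at that peak, and duration the
interval length. A cell participates when its own mean ΔF/F inside the
event exceeds its recording-wide mean (strict inequality, so a constant
cell never participates). Events recruiting more than 80% of cells are
H(igh-synchronicity) events; 20–80% (inclusive bounds) are L-events;
sparser intervals stay unclassified.

Two details deserve justification:

* **Interval vs binned scanning.** The historical procedure scans 6 s
  bins for candidate peaks and absorbs a candidate into a larger maximum
  in an adjacent bin, iterating until stable. Its fixed point — the set
  of super-threshold intervals containing a stable peak — is almost the
  set of all maximal super-threshold intervals, but a small interval
  whose bin maximum belongs to a neighbouring event is never seeded and
  silently vanishes. We therefore treat the interval enumeration as the
  reference semantics (`detect_events(method = "interval")`, the
  default) and keep the bin-scan as `method = "binned"`; the two agree
  whenever events are separated by more than a bin, and the reference
  semantics is the one verified against an independently written
  brute-force enumerator on randomised recordings.
* **Minimum duration.** Threshold crossings of a few frames are
  fluctuations of the population mean, not events — the events this
  analysis targets last roughly 2–20 s. A 1 s minimum duration
  (`min_duration_s`, config-exposed) is applied identically in the
  detector and the brute-force reference. Without it, study-scale
  simulations yield roughly two sub-second noise crossings per genuine
  event.

Event amplitude is the population-mean ΔF/F at the peak frame; a
per-participant alternative was considered and rejected because it
couples amplitude to the participation estimate. Edge-truncated events
are kept and flagged, but excluded from duration summaries, where they
would bias the mean downward.

## Correlations, responses, interneurons

Pairwise Pearson correlations are computed over full baseline traces;
zero-variance cells are excluded with a log message rather than an
error (they occur in short fixtures, and aborting a whole-recording
analysis for one silent ROI would be disproportionate). Distance
dependence uses left-closed 40 µm bins of inter-centroid Euclidean
distance, reporting per-bin means only where pairs exist.

Stimulus responsiveness pairs, per trial, the mean ΔF/F in the 1 s
before onset with the 1 s after. Pairing per trial (rather than testing
trial-averaged traces) is what gives the paired tests their n. The
paired differences pass a Shapiro–Wilk gate at the same α = 0.05:
normal cells get a paired t-test, the rest a Wilcoxon signed-rank test.
Benjamini–Hochberg correction is applied across all cells within one
stimulus type — the natural family, since recruitment ("proportion of
responsive neurons") is reported per stimulus type. Response amplitude
is the maximum ΔF/F in the 20 s post-stimulus window (the
inter-stimulus interval), so a peak at 21 s is deliberately invisible.

Interneurons are identified from the dedicated 20 s red-channel
recording as cells whose mean fluorescence is at or above the 97th
percentile of per-cell means — by construction a high-precision,
low-recall rule (≈3% of cells, `⌈0.03·n⌉ ± 1` under the interpolated
percentile convention). Cell–neuropil correlation is provided to
document the regime in which neuropil subtraction is *not* attempted:
at neonatal cell densities the cell–neuropil correlation approaches 1
and no stable correction factor exists.

## Sleep states from pose tracking

Movement is the frame-to-frame Euclidean displacement of each tracked
marker; scoring uses the left forelimb by default (the most reliably
visible marker). The qualitative criteria — continuous movement is
wake, immobility is quiet sleep (QS), isolated sharp twitches during
immobility mark active sleep (AS) — need quantitative commitments that
the underlying studies leave to the human scorer. The package's
defaults, all config-exposed and reported in the bout metadata:

| parameter | default | role |
|---|---|---|
| `theta_move` | 1.0 units/frame | immobility threshold |
| `median_filter_s` | 0.2 s | jitter suppression for wake detection |
| `max_twitch_s` | 0.5 s | longest excursion still counted as a twitch |
| `min_wake_s` | 1.0 s | shortest sustained-movement bout |
| `as_halo_s` | 2.5 s | sleep frames within this of a twitch are AS |

One asymmetry matters: wake is scored on the median-filtered
displacement, twitches on the raw displacement. A 0.2 s median filter
erases a 0.1 s twitch — which is precisely what makes it a good wake
detector and a useless twitch detector. The AS halo converts point-like
twitches into intervals; 2.5 s each way matches the twitch clustering
the generator plants (0.5 Hz during AS, a realistic neonatal myoclonic
rate) so that AS coverage is high without flooding adjacent QS. Bouts
tile the recording by construction, and scoring is invariant under
joint rescaling of coordinates and `theta_move`.

## Decoding with permutation-calibrated significance

Condition decoding works on post-stimulus trial tensors: for each 500 ms
bin of the 20 s post-stimulus window, each trial yields a vector of
per-cell bin means for a seed-fixed random subset of 500 cells (40 bins
× 500 features at full scale). One L2-penalised logistic classifier is
trained per stimulus type and time bin; the reported accuracy is the
maximum over bins on held-out data. The train/test split is
**subject-wise**: whole animals are assigned 60/40, so no animal
contributes trials to both sides, and the split is re-drawn (bounded)
until both conditions appear on both sides. The penalty weight defaults
to λ = 0.001 on the squared-coefficient term with an unpenalised
intercept; because "regularisation strength" follows a library-specific
convention in common usage, the inverse convention is exposed as
`penalty = "C"`.

Significance is calibrated by permutation: condition labels are
shuffled **at the animal level** (each animal's trials keep one common,
reassigned label — shuffling trials would break the within-animal
correlation that motivates subject-wise splitting in the first place),
the full per-bin pipeline is refit, and the max-over-bins accuracy of
each permuted fit forms the null sample. The threshold is the 95th
percentile (type-1, an order statistic) of that sample; decoding is
significant when the observed accuracy strictly exceeds it, and the
accuracy-minus-threshold margin is the effect-size-like summary. Full
runs use 7000 permutations; calibration experiments in the tests use
500, and verify that under a simulated global null the rejection rate
across 200 replicate experiments stays inside the binomial 95% interval
around 0.05.

The ridge-logistic solver is implemented in compiled code (damped
Newton/IRLS; exact dual solve via the kernel matrix when features
outnumber trials, as in the 300,000-feature stimulus-identity decoder).
The reason is arithmetic: calibration requires on the order of 10⁵
refits, and the solver is cross-checked coefficient-by-coefficient
against an independent penalised-regression implementation in the test
suite. The per-animal stimulus-type decoder flattens the full 20 s
window (500 cells × 600 frames) into one feature vector per trial and
uses one-vs-rest classification with leave-one-recording-out
cross-validation.

## LSPS maps and PSC features

Input maps are 11 × 17 grids of evoked synaptic charge at ~50 µm pitch.
`normalize_map()` divides by the total (unit mass, idempotent);
`columnar_profile()` and `layer_input_sums()` are exact partitions of
that mass, and `align_and_average_maps()` shifts maps so the L4/L5
boundary coincides before a per-pixel mean that reports contribution
counts alongside (boundary rows are covered by fewer maps and should be
read accordingly).

PSC feature extraction detects events in the 0–50 ms monosynaptic
window of baseline-subtracted sweeps (20 kHz). Onset is the first
crossing of 3 baseline SDs sustained for 0.5 ms, measured on a 0.5 ms
boxcar-smoothed copy; peak amplitude is read from the same lightly
smoothed trace (a raw max over thousands of samples is biased upward by
noise); charge integrates the raw trace from onset until a wider 2 ms
smoother stays within 1 SD of baseline for 1 ms (capped at 200 ms).
These estimator details were set by their recovery behaviour on planted
double-exponential PSCs (0.5 ms rise, 5 ms decay): at signal-to-noise 5
and above the suite verifies onset error ≤ 0.5 ms and mean charge error
≤ 5%. Polarity is a flag (`outward` for IPSCs at the glutamatergic
reversal potential, `inward` for EPSCs near rest); features are
reported as magnitudes.

## What the generator does and does not emulate

`simulate_recording()` builds traces as
`baseline × (1 + drive ⊗ kernel + shared noise + white noise)`:

* **kernel** — difference of exponentials, 0.18 s rise / 1.6 s decay,
  a slow-indicator (GCaMP6s-like) compromise; configurable because no
  indicator model is part of the analysis itself;
* **events** — a jittered regular schedule at 4/min with participation
  drawn uniformly on [0.2, 1] and peak ΔF/F ≈ 0.5 (±20%), spanning the
  L and H classes; ground-truth classes use the same thresholds as the
  detector so recovery is well-posed;
* **shared noise** — a low-rank Gaussian field (25 spatial bumps,
  exponential-family covariance, 100 µm length scale, AR(1) temporal
  factor) — the cheapest structure that produces a monotone
  distance–correlation curve;
* **white noise** — 5% of baseline per frame;
* **red channel** — continuous lognormal brightness with a planted 3%
  bright interneuron subset;
* **movement / serotonin** — state-dependent step statistics and
  baselines as described above.

Separate RNG substreams drive events, cell placement and noise, so
enlarging the population does not move event times. The generator does
*not* emulate pixel-level movies, motion artefacts, neuropil
contamination, indicator saturation, or slow drift; passing recovery
tests therefore demonstrates the correctness and calibration of the
analysis chain on data satisfying its assumptions, not robustness to
acquisition pathologies.

## Problem sizes and numerical choices

The verification suite uses deliberately chosen scales: 100 random
small recordings (≤20 cells × ≤3000 frames) for detector/brute-force
agreement; 50 study-scale recordings (200 cells, 10 min, 30 Hz) for
event recovery; 200 null recordings (100 cells, 10 trials) for FDR
calibration plus 10 recordings with responders planted at 3× the null
paired-difference SD for power; 200 replicate decoding experiments
(8 animals, 2 conditions, 10 trials each; 20 cells and 8 bins as the
feature scale; 500 permutations, scaled from the 7000 used in full
analyses) for null calibration, plus 20 seeds with a planted 1-SD
condition effect for the margin check; 50 seeded movement sessions for
sleep scoring; 40 planted sweeps at SNR 5–15 for PSC recovery. The same
computations back `scripts/acceptance.R`, which re-runs them from
scratch and writes the measured statistics as JSON.

Tie-breaks and degenerate inputs follow explicit conventions: event
peaks take the earliest argmax in an interval; a flat recording has no
events (its population mean never strictly exceeds itself); an
all-identical red channel flags every cell (the ≥ convention) with a
logged warning; quantile-edge cases in the permutation threshold
(α = 1) return the null minimum; optimizer tolerance is 10⁻⁶ with a
5000-iteration cap and step-halving for the rare separable split.

## Known limitations

* The binned event scan is provided for fidelity to the historical
  procedure but is not the verified reference path.
* Sleep-state thresholds are package conventions, not measured
  constants; on real pose data they should be checked against a
  manually scored segment.
* The permutation null for decoding assumes animals are exchangeable
  under the null; confounds correlated with condition (age, litter)
  are outside its reach.
* HDF5 container I/O is not provided; recordings travel as CSV or NPY
  plus CSV/YAML sidecars.
* Group-level statistics across animals (ANOVA families, omnibus
  tests) are intentionally out of scope; the package stops at
  per-recording and per-experiment quantities.
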