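#' Pairwise Pearson correlations between cells
#'
#' Correlation matrix of the full dF/F traces between all cell pairs.
#' Zero-variance cells cannot be correlated; they are excluded (rows and
#' columns set to NA) with a message, and an error is raised only when no
#' cell has variance.
#'
#' @param dff a `dff_recording` (or cells x frames matrix).
#' @return symmetric cells x cells matrix with unit diagonal (NA rows for
#'   excluded cells).
#' @export
pairwise_correlations <- function(dff) {
  m <- if (inherits(dff, "dff_recording")) dff$dff else as.matrix(dff)
  if (ncol(m) < 2L) stop("need >= 2 frames to correlate")
  v <- apply(m, 1, stats::var)
  ok <- v > 0
  if (!any(ok)) stop("all cells have zero variance")
  if (any(!ok))
    message("pairwise_correlations: excluding ", sum(!ok),
            " zero-variance cell(s): ",
            paste(which(!ok) - 1L, collapse = ", "))
  out <- matrix(NA_real_, nrow(m), nrow(m))
  out[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(out)[ok] <- 1
  out
}

#' Average correlation as a function of cell-pair distance
#'
#' Assigns every cell pair (i < j) to a distance bin by the Euclidean
#' distance between ROI centroids and averages the pairwise correlations
#' within each bin. Bins are contiguous, left-closed `[k*w, (k+1)*w)`
#' from 0, default width 40 um.
#'
#' @param corr cells x cells correlation matrix.
#' @param coords cells x 2 centroid matrix (um).
#' @param bin_um bin width in micrometres.
#' @return data.frame: `bin_low_um`, `bin_high_um`, `mean_correlation`
#'   (NA for bins without pairs), `n_pairs`.
#' @export
correlation_vs_distance <- function(corr, coords, bin_um = 40) {
  n <- nrow(corr)
  stopifnot(nrow(coords) == n)
  ut <- upper.tri(corr)
  d <- as.matrix(stats::dist(coords))[ut]
  r <- corr[ut]
  keep <- !is.na(r)
  d <- d[keep]; r <- r[keep]
  n_bins <- max(1L, ceiling(max(d, 0) / bin_um + 1e-9))
  bin <- pmin(floor(d / bin_um), n_bins - 1L) + 1L
  data.frame(
    bin_low_um = (seq_len(n_bins) - 1L) * bin_um,
    bin_high_um = seq_len(n_bins) * bin_um,
    mean_correlation = vapply(seq_len(n_bins), function(b) {
      if (any(bin == b)) mean(r[bin == b]) else NA_real_
    }, 0),
    n_pairs = vapply(seq_len(n_bins), function(b) sum(bin == b), 1L))
}

#' Compare two dF/F distributions
#'
#' Pools all dF/F samples of each recording and compares the two
#' distributions with a two-sample Kolmogorov-Smirnov test; empirical CDF
#' functions are returned for plotting cumulative probability curves.
#'
#' @param dff_a,dff_b `dff_recording`s or numeric matrices/vectors.
#' @return list: `ks_statistic`, `p_value`, `ecdf_a`, `ecdf_b`.
#' @export
cumulative_dff_comparison <- function(dff_a, dff_b) {
  a <- as.numeric(if (inherits(dff_a, "dff_recording")) dff_a$dff else dff_a)
  b <- as.numeric(if (inherits(dff_b, "dff_recording")) dff_b$dff else dff_b)
  if (!length(a) || !length(b)) stop("empty dF/F sample")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b))
}

# peri-stimulus window indices; NULL when the window leaves the recording
peristim_window <- function(onset, pre_f, post_f, n_t) {
  lo <- onset - pre_f; hi <- onset + post_f
  if (lo < 0L || hi > n_t) return(NULL)
  list(pre = if (pre_f > 0) (lo + 1L):onset else integer(),
       post = (onset + 1L):hi)
}

#' Stimulus-triggered average response
#'
#' Mean +/- SEM peri-stimulus dF/F per stimulus type, averaged over trials
#' and cells. Each trial snippet is baseline-aligned by subtracting its
#' pre-window mean. Trials whose window leaves the recording are dropped
#' with a message.
#'
#' @param dff a `dff_recording`.
#' @param stim_log a [stimulus_log()].
#' @param pre_s,post_s window extent around the onset, seconds.
#' @return named list per stimulus type: `time_s`, `mean`, `sem`,
#'   `n_trials`.
#' @export
stimulus_triggered_average <- function(dff, stim_log, pre_s = 2, post_s = 20) {
  fs <- dff$frame_rate
  pre_f <- round(pre_s * fs); post_f <- round(post_s * fs)
  n_t <- ncol(dff$dff)
  types <- unique(stim_log$stimulus_type)
  out <- stats::setNames(vector("list", length(types)), types)
  for (ty in types) {
    onsets <- stim_log$onset_frame[stim_log$stimulus_type == ty]
    snips <- list()
    for (on in onsets) {
      w <- peristim_window(on, pre_f, post_f, n_t)
      if (is.null(w)) next
      snip <- dff$dff[, c(w$pre, w$post), drop = FALSE]
      base <- rowMeans(dff$dff[, w$pre, drop = FALSE])
      snips[[length(snips) + 1L]] <- sweep(snip, 1, base)
    }
    if (length(snips) < length(onsets))
      message("stimulus_triggered_average: dropped ",
              length(onsets) - length(snips), " edge trial(s) for ", ty)
    if (!length(snips)) stop("no valid trials for stimulus type ", ty)
    stk <- do.call(rbind, snips)          # (trials*cells) x frames
    out[[ty]] <- list(
      time_s = (seq_len(pre_f + post_f) - pre_f - 1L) / fs,
      mean = colMeans(stk),
      sem = apply(stk, 2, stats::sd) / sqrt(nrow(stk)),
      n_trials = length(snips))
  }
  out
}

#' Per-cell, per-trial stimulus response amplitude
#'
#' Response amplitude is the maximum dF/F within the post-stimulus window
#' (default 20 s, i.e. within the inter-stimulus interval). Trials whose
#' window would leave the recording are dropped.
#'
#' @param dff a `dff_recording`.
#' @param stim_log a [stimulus_log()].
#' @param window_s post-stimulus window length, seconds.
#' @return data.frame: `stimulus_type`, `trial`, `cell`, `amplitude`.
#' @export
response_amplitude <- function(dff, stim_log, window_s = 20) {
  fs <- dff$frame_rate
  post_f <- round(window_s * fs)
  n_t <- ncol(dff$dff)
  rows <- list()
  for (ty in unique(stim_log$stimulus_type)) {
    onsets <- stim_log$onset_frame[stim_log$stimulus_type == ty]
    tr <- 0L
    for (on in onsets) {
      w <- peristim_window(on, 0L, post_f, n_t)
      if (is.null(w)) next
      tr <- tr + 1L
      amp <- apply(dff$dff[, w$post, drop = FALSE], 1, max)
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus_type = ty, trial = tr, cell = seq_along(amp) - 1L,
        amplitude = amp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Test per-cell stimulus responsiveness
#'
#' For each cell and stimulus type, pairs the mean dF/F in the 1 s before
#' each onset with the mean in the 1 s after it, across trials. Normality
#' of the paired differences is assessed with the Shapiro-Wilk test at
#' `alpha`; normal cells use a paired t-test, the rest a Wilcoxon
#' signed-rank test. P-values are Benjamini-Hochberg corrected across all
#' cells within each stimulus type, and a cell is responsive when its
#' adjusted p-value is below `alpha`. Neuronal recruitment is the
#' proportion of responsive cells.
#'
#' @param dff a `dff_recording`.
#' @param stim_log a [stimulus_log()].
#' @param pre_s,post_s paired-window lengths, seconds.
#' @param alpha significance (and normality-gate) level.
#' @return data.frame: `stimulus_type`, `cell`, `n_trials`, `normal`,
#'   `test`, `p_raw`, `p_adj`, `responsive`; per-type recruitment
#'   fractions in `attr(, "recruitment")`.
#' @export
responsiveness_test <- function(dff, stim_log, pre_s = 1, post_s = 1,
                                alpha = 0.05) {
  fs <- dff$frame_rate
  pre_f <- round(pre_s * fs); post_f <- round(post_s * fs)
  n_t <- ncol(dff$dff); n_c <- nrow(dff$dff)
  res <- list()
  for (ty in unique(stim_log$stimulus_type)) {
    onsets <- stim_log$onset_frame[stim_log$stimulus_type == ty]
    wins <- Filter(Negate(is.null),
                   lapply(onsets, peristim_window, pre_f, post_f, n_t))
    if (length(wins) < 2L)
      stop("responsiveness_test: need >= 2 valid trials for ", ty)
    pre_m <- vapply(wins, function(w)
      rowMeans(dff$dff[, w$pre, drop = FALSE]), numeric(n_c))
    post_m <- vapply(wins, function(w)
      rowMeans(dff$dff[, w$post, drop = FALSE]), numeric(n_c))
    if (n_c == 1L) { pre_m <- rbind(pre_m); post_m <- rbind(post_m) }
    cell_rows <- lapply(seq_len(n_c), function(c) {
      d <- post_m[c, ] - pre_m[c, ]
      normal <- if (stats::sd(d) == 0) FALSE
                else stats::shapiro.test(d)$p.value >= alpha
      p <- if (all(d == 0)) 1
      else if (normal)
        stats::t.test(post_m[c, ], pre_m[c, ], paired = TRUE)$p.value
      else
        suppressWarnings(stats::wilcox.test(post_m[c, ], pre_m[c, ],
                                            paired = TRUE))$p.value
      data.frame(stimulus_type = ty, cell = c - 1L,
                 n_trials = length(d), normal = normal,
                 test = if (normal) "paired_t" else "wilcoxon",
                 p_raw = if (is.na(p)) 1 else p,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, cell_rows)
    df$p_adj <- stats::p.adjust(df$p_raw, method = "BH")
    df$responsive <- df$p_adj < alpha
    res[[ty]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "recruitment") <- vapply(res, function(df)
    mean(df$responsive), 0)
  out
}

#' Identify interneurons from the red structural channel
#'
#' Cells are flagged as interneurons when their mean red (tdTomato)
#' fluorescence over the dedicated 20 s 765 nm recording is equal to or
#' higher than the given percentile (default 97th) of the per-cell means
#' — a conservative rule tuned to minimise false positives, identifying a
#' bright subset rather than every interneuron.
#'
#' @param red red-channel [fluorescence_recording()].
#' @param percentile threshold percentile of the per-cell means.
#' @return logical mask, one flag per cell.
#' @export
identify_interneurons <- function(red, percentile = 97) {
  stopifnot(inherits(red, "fluor_recording"))
  means <- rowMeans(red$raw)
  thr <- stats::quantile(means, percentile / 100, names = FALSE, type = 7)
  mask <- means >= thr
  if (all(mask))
    message("identify_interneurons: all cells at/above the ",
            percentile, "th percentile (degenerate red channel)")
  mask
}

#' Correlation between a cell trace and its surrounding neuropil
#'
#' Pearson correlation over the full baseline traces; used to document
#' why neuropil subtraction is omitted (near-unity correlations make a
#' stable correction factor unidentifiable at high cell density).
#'
#' @param cell_trace,neuropil_trace equal-length numeric vectors.
#' @return scalar r, or NA with a warning if either trace has zero
#'   variance.
#' @export
cell_neuropil_correlation <- function(cell_trace, neuropil_trace) {
  if (length(cell_trace) != length(neuropil_trace))
    stop("traces differ in length")
  if (stats::sd(cell_trace) == 0 || stats::sd(neuropil_trace) == 0) {
    warning("zero-variance trace; correlation undefined")
    return(NA_real_)
  }
  stats::cor(cell_trace, neuropil_trace)
}
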