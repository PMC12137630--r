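#' LSPS input map
#'
#' Grid of mean evoked synaptic charge (pC) per laser-scanning
#' photostimulation position: 11 rows x 17 columns by default, spots
#' spaced ~50 um, rows ordered pia to white matter. Layer geometry is a
#' named list mapping each layer label to its (0-based) row indices;
#' ranges must be disjoint and cover distinct rows in pial order.
#'
#' @param grid numeric matrix of rectified (>= 0) charges.
#' @param layer_rows named list layer -> integer vector of 0-based rows.
#' @param row_spacing_um grid pitch, micrometres.
#' @param soma_position optional `(row, col)`, 0-based.
#' @return matrix of class `lsps_map` with geometry attributes.
#' @export
lsps_map <- function(grid, layer_rows = NULL, row_spacing_um = 50,
                     soma_position = NULL) {
  grid <- as.matrix(grid)
  if (any(grid < 0)) stop("charges must be >= 0 after rectification")
  if (!is.null(layer_rows)) {
    all_rows <- unlist(layer_rows)
    if (anyDuplicated(all_rows))
      stop("layer row ranges must be disjoint")
    if (any(all_rows < 0 | all_rows >= nrow(grid)))
      stop("layer rows outside the grid")
    if (is.unsorted(vapply(layer_rows, min, 0)))
      stop("layers must be ordered pia to white matter")
  }
  structure(grid, layer_rows = layer_rows,
            row_spacing_um = row_spacing_um,
            soma_position = soma_position, class = c("lsps_map", "matrix"))
}

map_attrs <- function(m) list(layer_rows = attr(m, "layer_rows"),
                              row_spacing_um = attr(m, "row_spacing_um"),
                              soma_position = attr(m, "soma_position"))

#' Normalise an LSPS map to unit total input
#'
#' Divides each laser position's input by the sum over all pixels, so
#' normalised pixel values sum to 1 and maps from different cells are
#' comparable. Idempotent.
#'
#' @param m an [lsps_map()].
#' @return normalised `lsps_map`.
#' @export
normalize_map <- function(m) {
  tot <- sum(m)
  if (tot <= 0) stop("cannot normalise an all-zero map")
  out <- unclass(m) / tot
  do.call(lsps_map, c(list(out), map_attrs(m)))
}

#' Columnar profile of an LSPS map
#'
#' Sums all values of each grid row (depth line), giving the laminar
#' profile of input as a function of cortical depth. Conserves the map
#' total.
#'
#' @param m an [lsps_map()].
#' @return numeric vector of per-row sums (pia first).
#' @export
columnar_profile <- function(m) rowSums(m)

#' Per-layer input totals
#'
#' Sums all inputs over the pixels belonging to each cortical layer
#' (boundaries determined from the DIC image and supplied as
#' `layer_rows`). Totals over layers equal the map total exactly.
#'
#' @param m an [lsps_map()] with `layer_rows` set.
#' @return named numeric vector of per-layer totals.
#' @export
layer_input_sums <- function(m) {
  lr <- attr(m, "layer_rows")
  if (is.null(lr)) stop("map has no layer_rows geometry")
  covered <- sort(as.integer(unlist(lr, use.names = FALSE)))
  if (!identical(covered, 0:(nrow(m) - 1L)))
    stop("layer_rows must cover every grid row exactly once; missing: ",
         paste(setdiff(0:(nrow(m) - 1L), covered), collapse = ", "))
  vapply(lr, function(rows) sum(m[rows + 1L, , drop = FALSE]), 0)
}

#' Align maps at the L4-L5 boundary and average
#'
#' Shifts each map vertically so the base of layer 4 (the L4/L5 boundary
#' row) coincides across maps, pads out-of-range rows with NA, and takes
#' the per-pixel mean over available values. The per-pixel number of
#' contributing maps is returned alongside so sparsely covered boundary
#' rows remain interpretable.
#'
#' @param maps list of [lsps_map()]s, each with layers `L4` and `L5`
#'   (or `L5a`) in its geometry.
#' @return list: `mean` (aligned average map, rows indexed relative to
#'   the common boundary), `n` (per-pixel contribution counts),
#'   `boundary_row` (0-based row of the boundary in the output).
#' @export
align_and_average_maps <- function(maps) {
  boundary <- vapply(maps, function(m) {
    lr <- attr(m, "layer_rows")
    if (is.null(lr) || is.null(lr$L4))
      stop("every map needs an L4 layer range to align on")
    max(lr$L4) + 1L              # first infragranular row
  }, 1L)
  n_col <- vapply(maps, ncol, 1L)
  if (length(unique(n_col)) != 1L) stop("maps differ in column count")
  up <- max(boundary)                       # rows above boundary
  down <- max(vapply(maps, nrow, 1L) - boundary)
  n_rows <- up + down
  if (n_rows <= 0L) stop("no overlap after alignment")
  acc <- matrix(0, n_rows, n_col[1L])
  cnt <- matrix(0L, n_rows, n_col[1L])
  for (i in seq_along(maps)) {
    off <- up - boundary[i]
    rows <- (off + 1L):(off + nrow(maps[[i]]))
    acc[rows, ] <- acc[rows, ] + unclass(maps[[i]])
    cnt[rows, ] <- cnt[rows, ] + 1L
  }
  avg <- acc / cnt
  avg[cnt == 0L] <- NA_real_
  list(mean = avg, n = cnt, boundary_row = up)
}

#' Extract postsynaptic-current features from a sweep
#'
#' Detects an evoked PSC in the monosynaptic window (default 0-50 ms from
#' stimulus onset) of a voltage-clamp sweep and measures peak amplitude,
#' charge (area under the curve) and onset latency. The sweep is
#' baseline-subtracted (mean over `baseline_window`); polarity is set by
#' `direction` (IPSCs recorded at E_Glut are outward/positive, EPSCs near
#' RMP negative) and features are reported as magnitudes.
#'
#' Onset is the first crossing of `onset_k_sd` baseline SDs (on a short
#' boxcar-smoothed copy of the trace) sustained for `onset_sustain_ms`;
#' sweeps with no such crossing inside the window are failures. Peak
#' amplitude is read from the lightly smoothed trace (noise maxima over
#' thousands of samples would otherwise bias the raw maximum upward).
#' Charge is integrated (trapezoid) from onset until the current — on a
#' wider `return_smooth_ms` smoother — first stays within `return_k_sd`
#' smoothed-baseline SDs of baseline for `return_sustain_ms`, capped at
#' `max_integration_ms`.
#'
#' @param sweep numeric current trace (pA).
#' @param stim_onset stimulus onset, in samples (0-based).
#' @param sample_rate sampling rate, Hz (acquisition at 20 kHz).
#' @param window_ms onset detection window relative to the stimulus, ms.
#' @param baseline_window `(start, end)` samples (0-based, half-open)
#'   used for the baseline; default the 50 ms before the stimulus.
#' @param direction `"outward"` (IPSC, positive) or `"inward"` (EPSC).
#' @param onset_k_sd,onset_sustain_ms,smooth_ms,return_k_sd,return_smooth_ms,return_sustain_ms,max_integration_ms
#'   detector parameters (see above).
#' @return list of class `psc_features`: `is_failure`, `onset_ms` (from
#'   stimulus onset), `peak_amplitude_pa`, `charge_pc`, `direction`.
#' @export
extract_psc_features <- function(sweep, stim_onset, sample_rate = 20000,
                                 window_ms = c(0, 50),
                                 baseline_window = NULL,
                                 direction = c("outward", "inward"),
                                 onset_k_sd = 3, onset_sustain_ms = 0.5,
                                 smooth_ms = 0.5, return_k_sd = 1,
                                 return_smooth_ms = 2, return_sustain_ms = 1,
                                 max_integration_ms = 200) {
  direction <- match.arg(direction)
  n <- length(sweep)
  ms <- sample_rate / 1000                  # samples per ms
  if (is.null(baseline_window))
    baseline_window <- c(max(0L, stim_onset - round(50 * ms)), stim_onset)
  bidx <- frames_in(baseline_window[1L], baseline_window[2L])
  win <- stim_onset + round(window_ms * ms)
  if (win[1L] < 0L || win[2L] > n)
    stop("detection window [", win[1L], ", ", win[2L],
         ") outside sweep of length ", n)
  x <- sweep - mean(sweep[bidx])
  if (direction == "inward") x <- -x
  w <- max(1L, round(smooth_ms * ms))
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  sd_s <- stats::sd(xs[bidx])
  if (sd_s == 0) sd_s <- .Machine$double.eps

  sustain <- max(1L, round(onset_sustain_ms * ms))
  widx <- frames_in(win[1L], win[2L])
  over <- xs[widx] > onset_k_sd * sd_s
  onset_rel <- NA_integer_
  r <- rle(over)
  pos <- cumsum(r$lengths) - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain)
  if (length(hit)) onset_rel <- pos[hit[1L]]
  if (is.na(onset_rel))
    return(structure(list(is_failure = TRUE, onset_ms = NA_real_,
                          peak_amplitude_pa = NA_real_,
                          charge_pc = NA_real_, direction = direction),
                     class = "psc_features"))
  onset <- widx[onset_rel]                   # 1-based sample index

  wr <- max(1L, round(return_smooth_ms * ms))
  xr <- as.numeric(stats::filter(x, rep(1 / wr, wr), sides = 2))
  xr[is.na(xr)] <- x[is.na(xr)]
  sd_r <- max(stats::sd(xr[bidx]), .Machine$double.eps)
  stop_cap <- min(n, onset + round(max_integration_ms * ms))
  after <- onset:stop_cap
  below <- xr[after] < return_k_sd * sd_r
  rb <- rle(below)
  rpos <- cumsum(rb$lengths) - rb$lengths + 1L
  rhit <- which(rb$values & rb$lengths >= round(return_sustain_ms * ms))
  end <- if (length(rhit)) after[rpos[rhit[1L]]] else stop_cap
  seg <- onset:end
  peak_idx <- seg[which.max(xs[seg])]
  dt_ms <- 1 / ms
  charge <- sum((x[seg][-1] + x[seg][-length(seg)]) / 2) * dt_ms  # pA*ms
  structure(list(
    is_failure = FALSE,
    onset_ms = (onset - 1L - stim_onset) * dt_ms,
    peak_amplitude_pa = xs[peak_idx],
    charge_pc = charge / 1000,               # pA*ms -> pC
    direction = direction), class = "psc_features")
}

#' Summarise minimal-stimulation sweeps
#'
#' Failure rate and success-trial feature means over repeated minimal
#' optogenetic stimulation sweeps (>= 6 trials; minimal stimulation is
#' titrated to ~50% failures as a proxy for unitary input).
#'
#' @param sweeps list of `psc_features`.
#' @return data.frame: `n_sweeps`, `failure_rate`,
#'   `mean_amplitude_pa`, `mean_charge_pc` (NA when every sweep failed).
#' @export
minimal_input_summary <- function(sweeps) {
  if (length(sweeps) < 6L)
    warning("minimal-stimulation summaries expect >= 6 trials, got ",
            length(sweeps))
  fail <- vapply(sweeps, `[[`, TRUE, "is_failure")
  ok <- sweeps[!fail]
  data.frame(
    n_sweeps = length(sweeps),
    failure_rate = mean(fail),
    mean_amplitude_pa = if (length(ok))
      mean(vapply(ok, `[[`, 0, "peak_amplitude_pa")) else NA_real_,
    mean_charge_pc = if (length(ok))
      mean(vapply(ok, `[[`, 0, "charge_pc")) else NA_real_)
}

#' Read/write an LSPS map as CSV plus a JSON geometry sidecar
#'
#' The grid is a plain CSV matrix (no header); `<stem>_layers.json`
#' holds `layer_rows`, `row_spacing_um` and `soma_position`.
#'
#' @param m an [lsps_map()]; `path` the grid CSV path.
#' @export
write_lsps_map <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- paste0(sub("\\.[^.]+$", "", path), "_layers.json")
  at <- map_attrs(m)
  jsonlite::write_json(at, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_lsps_map
#' @param path grid CSV path.
#' @export
read_lsps_map <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(grid) <- NULL
  side <- paste0(sub("\\.[^.]+$", "", path), "_layers.json")
  at <- if (file.exists(side)) jsonlite::read_json(side,
                                                   simplifyVector = TRUE)
        else list()
  lr <- if (!is.null(at$layer_rows))
    lapply(at$layer_rows, as.integer) else NULL
  lsps_map(grid, lr, at$row_spacing_um %||% 50, at$soma_position)
}
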