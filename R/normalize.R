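#' dF/F normalisation
#'
#' Two baselining variants are provided. `dff_mean_baseline()` computes
#' `(F - Fmean) / Fmean` with `Fmean` the per-cell mean over a baseline
#' window (by default the whole recording) — the convention used for
#' sensor traces and adult recordings. `dff_percentile()` computes
#' `(F - F_p) / F_p` with `F_p` the per-cell first percentile of raw
#' fluorescence across the whole recording — the convention used for
#' developmental calcium recordings, where a low-percentile baseline is
#' stable against the changing calcium physiology across age. Percentiles
#' use linear interpolation between order statistics (`stats::quantile`
#' type 7); the convention is recorded in the result's provenance.
#'
#' Both variants are invariant under positive rescaling of the raw
#' fluorescence and map constant traces to zero.
#'
#' @param rec a [fluorescence_recording()].
#' @param baseline half-open frame window `c(start, end)` (0-based) over
#'   which the per-cell mean is taken; `NULL` = whole recording.
#' @param percentile baseline percentile (default 1 = first percentile).
#' @return A `dff_recording`: list with `dff` (cells x frames matrix),
#'   `coords`, `frame_rate`, and `provenance`.
#' @export
dff_mean_baseline <- function(rec, baseline = NULL) {
  stopifnot(inherits(rec, "fluor_recording"))
  idx <- if (is.null(baseline)) seq_len(n_frames(rec))
         else frames_in(baseline[1L], min(baseline[2L], n_frames(rec)))
  f0 <- rowMeans(rec$raw[, idx, drop = FALSE])
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("nonpositive baseline mean for cell(s) ",
         paste(bad[seq_len(min(5, length(bad)))] - 1L, collapse = ", "))
  new_dff(sweep(rec$raw, 1, f0, "/") - 1, rec,
          list(method = "mean_baseline",
               baseline = if (is.null(baseline)) c(0L, n_frames(rec))
                          else baseline))
}

#' @rdname dff_mean_baseline
#' @export
dff_percentile <- function(rec, percentile = 1) {
  stopifnot(inherits(rec, "fluor_recording"),
            percentile > 0, percentile < 100)
  f0 <- apply(rec$raw, 1, stats::quantile, probs = percentile / 100,
              names = FALSE, type = 7)
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("nonpositive ", percentile, "th-percentile baseline for cell(s) ",
         paste(bad[seq_len(min(5, length(bad)))] - 1L, collapse = ", "))
  new_dff(sweep(rec$raw, 1, f0, "/") - 1, rec,
          list(method = "first_percentile", percentile = percentile,
               quantile_type = 7))
}

new_dff <- function(dff, rec, provenance) {
  structure(list(dff = dff, coords = rec$coords,
                 frame_rate = rec$frame_rate, provenance = provenance),
            class = "dff_recording")
}

#' @export
print.dff_recording <- function(x, ...) {
  cat(sprintf("<dff_recording> %d cells x %d frames @ %g Hz (%s)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate,
              x$provenance$method))
  invisible(x)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing of a 1-D signal, default a
#' third-order polynomial on 31-frame windows (~1 s at 30 Hz), as used for
#' serotonin-sensor traces. Edges are mirror-padded so short traces show
#' no boundary transients. An order-`polyorder` filter reproduces
#' polynomial segments of degree <= `polyorder` exactly and commutes with
#' adding constants.
#'
#' @param trace numeric vector.
#' @param window_frames odd window length, `> polyorder` and
#'   `<= length(trace)`.
#' @param polyorder polynomial order (default 3).
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(trace, window_frames = 31L, polyorder = 3L) {
  n <- length(trace)
  if (window_frames %% 2 == 0)
    stop("window_frames must be odd, got ", window_frames)
  if (window_frames <= polyorder)
    stop("window_frames (", window_frames, ") must exceed polyorder (",
         polyorder, ")")
  if (window_frames > n)
    stop("window_frames (", window_frames, ") exceeds trace length (", n, ")")
  half <- (window_frames - 1L) %/% 2L
  # central-row projection coefficients from the signal package
  coef <- signal::sgolay(p = polyorder, n = window_frames)[half + 1L, ]
  padded <- c(trace[(half + 1L):2L], trace, trace[(n - 1L):(n - half)])
  out <- stats::filter(padded, rev(coef), sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Ratiometric correction against a control channel
#'
#' Removes hemodynamic (activity-independent) fluorescence changes from a
#' sensor trace using the co-expressed red structural channel. The default
#' subtracts the control channel's fractional change
#' (`green_dff - red_dff`); `mode = "divide"` instead divides the raw
#' ratios, `(1 + green_dff) / (1 + red_dff) - 1`. Applied to stimulus
#' responses from P14 on, when hemodynamic responses become visible.
#'
#' @param green_dff,red_dff equal-length dF/F vectors.
#' @param mode `"subtract"` (default) or `"divide"`.
#' @return Corrected dF/F vector.
#' @export
ratiometric_correct <- function(green_dff, red_dff,
                                mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  if (length(green_dff) != length(red_dff))
    stop("green (", length(green_dff), ") and red (", length(red_dff),
         ") traces differ in length")
  switch(mode,
         subtract = green_dff - red_dff,
         divide = (1 + green_dff) / (1 + red_dff) - 1)
}

#' Subregion-grid mean traces
#'
#' Tiles each image of a frame stack into a `grid[1] x grid[2]` grid
#' (default 16 x 16 = 256 subregions) and returns the per-frame mean
#' intensity of every tile. When the image size is not divisible by the
#' grid, the last tile in each dimension absorbs the remainder; the tile
#' geometry is attached as an attribute.
#'
#' @param frame_stack 3-D array `height x width x frames`.
#' @param grid integer `(rows, cols)`.
#' @return matrix `(grid[1] * grid[2]) x frames`, tiles in row-major
#'   order, with attribute `tiles` (per-tile pixel bounds).
#' @export
subregion_grid_means <- function(frame_stack, grid = c(16L, 16L)) {
  d <- dim(frame_stack)
  if (length(d) != 3L) stop("frame_stack must be height x width x frames")
  if (grid[1L] > d[1L] || grid[2L] > d[2L])
    stop("grid ", grid[1L], " x ", grid[2L],
         " exceeds image size ", d[1L], " x ", d[2L])
  rb <- floor(seq(0L, d[1L], length.out = grid[1L] + 1L))
  cb <- floor(seq(0L, d[2L], length.out = grid[2L] + 1L))
  # edge-inclusive tiling: boundaries cover the full image
  rb[grid[1L] + 1L] <- d[1L]; cb[grid[2L] + 1L] <- d[2L]
  n_tiles <- grid[1L] * grid[2L]
  out <- matrix(0, n_tiles, d[3L])
  tiles <- vector("list", n_tiles)
  k <- 0L
  for (i in seq_len(grid[1L])) {
    for (j in seq_len(grid[2L])) {
      k <- k + 1L
      rows <- (rb[i] + 1L):rb[i + 1L]
      cols <- (cb[j] + 1L):cb[j + 1L]
      out[k, ] <- apply(frame_stack[rows, cols, , drop = FALSE], 3, mean)
      tiles[[k]] <- c(row0 = rb[i], row1 = rb[i + 1L],
                      col0 = cb[j], col1 = cb[j + 1L])
    }
  }
  attr(out, "tiles") <- tiles
  out
}
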