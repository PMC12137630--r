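#' Fluorescence recording container
#'
#' Bundles a cells x frames raw-fluorescence matrix with per-cell ROI
#' centroid coordinates (micrometres within the field of view), the
#' acquisition frame rate and free-form metadata. This is the common
#' currency of the pipeline: trace extraction (e.g. suite2p) happens
#' upstream; everything downstream (normalisation, event detection,
#' correlations, decoding) consumes this object.
#'
#' Frames are 0-based throughout the package and all frame windows are
#' half-open `[start, end)`.
#'
#' @param raw numeric matrix, cells x frames, raw fluorescence (a.u.).
#' @param coords numeric matrix or data.frame with one `(x, y)` row per
#'   cell, in micrometres; origin at the upper-left of the field of view.
#' @param frame_rate acquisition rate in Hz (default 30).
#' @param channel label of the imaged channel, `"green"` or `"red"`.
#' @param metadata named list of free-form strings (animal id, age,
#'   condition, ...).
#' @return An object of class `fluor_recording`.
#' @export
fluorescence_recording <- function(raw, coords = NULL, frame_rate = 30,
                                   channel = c("green", "red"),
                                   metadata = list()) {
  channel <- match.arg(channel)
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (nrow(raw) < 1L || ncol(raw) < 2L)
    stop("recording needs >= 1 cell and >= 2 frames, got ",
         nrow(raw), " x ", ncol(raw))
  bad <- which(!is.finite(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite fluorescence at cell ", bad[1L, 1L] - 1L,
         ", frame ", bad[1L, 2L] - 1L,
         if (nrow(bad) > 1L) paste0(" (and ", nrow(bad) - 1L, " more)") else "")
  if (is.null(coords)) {
    coords <- matrix(NA_real_, nrow(raw), 2L)
  } else {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }
  if (nrow(coords) != nrow(raw) || ncol(coords) != 2L)
    stop("coords must be one (x, y) row per cell: expected ",
         nrow(raw), " x 2, got ", nrow(coords), " x ", ncol(coords))
  colnames(coords) <- c("x", "y")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  structure(
    list(raw = raw, coords = coords, frame_rate = as.numeric(frame_rate),
         channel = channel, metadata = metadata),
    class = "fluor_recording"
  )
}

#' @export
print.fluor_recording <- function(x, ...) {
  cat(sprintf(
    "<fluor_recording> %d cells x %d frames @ %g Hz (%.1f min), channel %s\n",
    n_cells(x), n_frames(x), x$frame_rate,
    n_frames(x) / x$frame_rate / 60, x$channel))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fluorescence_recording
#' @param rec a `fluor_recording`.
#' @export
n_cells <- function(rec) nrow(rec$raw)

#' @rdname fluorescence_recording
#' @export
n_frames <- function(rec) ncol(rec$raw)

# ---- NPY (minimal v1.0, 2-D double, C order) --------------------------------
# No installed R package reads .npy, so a minimal reader/writer for the one
# dtype/layout the pipeline uses lives here.

write_npy_matrix <- function(m, path) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  invisible(path)
}

read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'descr':\\s*'<f8'", header))
    stop("unsupported NPY dtype (need little-endian float64) in ", path)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([0-9]+)\\s*,\\s*([0-9]+)\\s*,?\\)", header))
  if (!length(shp)) stop("NPY file is not a 2-D array: ", path)
  dims <- as.integer(strsplit(gsub("[()\\s]", "", shp, perl = TRUE), ",")[[1]])
  vals <- readBin(con, "double", prod(dims), size = 8L, endian = "little")
  if (fortran) matrix(vals, dims[1L], dims[2L])
  else t(matrix(vals, dims[2L], dims[1L]))
}

# ---- recording I/O ----------------------------------------------------------

#' Read and write fluorescence recordings
#'
#' Two on-disk layouts are supported. `format = "csv"`: `<path>` is a CSV
#' matrix of traces (cells x frames, no header) and `<path stem>_coords.csv`
#' holds columns `x,y`; a `<path stem>_meta.yaml` sidecar (frame_rate,
#' channel, metadata) is read when present. `format = "npy"`: same layout
#' with the trace matrix as a NumPy `.npy` (2-D float64) file.
#'
#' @param path trace-matrix file path.
#' @param format `"csv"` or `"npy"`.
#' @return `read_recording` returns a validated [fluorescence_recording()];
#'   `write_recording` returns `path` invisibly after writing the matrix,
#'   the coordinate CSV and the metadata sidecar.
#' @export
read_recording <- function(path, format = c("csv", "npy")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- switch(format,
    csv = unname(as.matrix(data.table::fread(path, header = FALSE))),
    npy = read_npy_matrix(path))
  stem <- sub("\\.[^.]+$", "", path)
  cpath <- paste0(stem, "_coords.csv")
  coords <- NULL
  if (file.exists(cpath)) {
    cdf <- utils::read.csv(cpath)
    if (!all(c("x", "y") %in% names(cdf)))
      stop("coordinate file ", cpath, " must have columns x,y")
    coords <- as.matrix(cdf[, c("x", "y")])
  }
  frame_rate <- 30; channel <- "green"; metadata <- list()
  mpath <- paste0(stem, "_meta.yaml")
  if (file.exists(mpath)) {
    meta <- yaml::read_yaml(mpath)
    if (!is.null(meta$frame_rate)) frame_rate <- meta$frame_rate
    if (!is.null(meta$channel)) channel <- meta$channel
    if (!is.null(meta$metadata)) metadata <- meta$metadata
  }
  fluorescence_recording(raw, coords, frame_rate, channel, metadata)
}

#' @rdname read_recording
#' @param rec a `fluor_recording` to write.
#' @export
write_recording <- function(rec, path, format = c("csv", "npy")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "fluor_recording"))
  switch(format,
    csv = data.table::fwrite(data.table::as.data.table(rec$raw), path,
                             col.names = FALSE),
    npy = write_npy_matrix(rec$raw, path))
  stem <- sub("\\.[^.]+$", "", path)
  utils::write.csv(as.data.frame(rec$coords), paste0(stem, "_coords.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(frame_rate = rec$frame_rate, channel = rec$channel,
                        metadata = rec$metadata),
                   paste0(stem, "_meta.yaml"))
  invisible(path)
}

# ---- stimulus log -----------------------------------------------------------

known_stimulus_types <- c("single_whisker", "multi_whisker", "airpuff",
                          "auditory", "smooth", "rough")

#' Stimulus log
#'
#' A table of stimulus onsets: `onset_frame` (0-based, strictly increasing)
#' and `stimulus_type`. Stimuli in the experimental battery are
#' single-whisker, multi-whisker, airpuff, auditory and smooth/rough
#' textures, delivered ~10 times each with 20-30 s inter-stimulus
#' intervals; unknown labels are kept but flagged with a message.
#'
#' @param onset_frame integer vector of 0-based onset frames.
#' @param stimulus_type character vector of stimulus labels.
#' @param n_frames optional recording length used to bound-check onsets.
#' @return A `data.frame` of class `stimulus_log`.
#' @export
stimulus_log <- function(onset_frame = integer(), stimulus_type = character(),
                         n_frames = NULL) {
  onset_frame <- as.integer(onset_frame)
  stimulus_type <- as.character(stimulus_type)
  if (length(onset_frame) != length(stimulus_type))
    stop("onset_frame and stimulus_type lengths differ")
  if (length(onset_frame) > 1L && any(diff(onset_frame) <= 0))
    stop("stimulus onsets must be strictly increasing")
  if (any(onset_frame < 0L))
    stop("stimulus onsets must be >= 0")
  if (!is.null(n_frames) && any(onset_frame >= n_frames))
    stop("stimulus onset beyond recording length (", n_frames, " frames)")
  unknown <- setdiff(unique(stimulus_type), known_stimulus_types)
  if (length(unknown))
    message("stimulus_log: unrecognised stimulus type(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  structure(data.frame(onset_frame = onset_frame,
                       stimulus_type = stimulus_type,
                       stringsAsFactors = FALSE),
            class = c("stimulus_log", "data.frame"))
}

#' @rdname stimulus_log
#' @param path CSV path with columns `onset_frame,stimulus_type` (header
#'   optional).
#' @export
read_stimulus_log <- function(path, n_frames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(stimulus_log())
  header <- grepl("onset_frame", first, fixed = TRUE)
  df <- utils::read.csv(path, header = header,
                        col.names = c("onset_frame", "stimulus_type"))
  stimulus_log(df$onset_frame, trimws(df$stimulus_type), n_frames)
}

#' @rdname stimulus_log
#' @param log a `stimulus_log`.
#' @export
write_stimulus_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

# ---- results tables ---------------------------------------------------------

#' Write a list of keyed result records as a CSV table
#'
#' Every record must carry the same keys (column set); column order follows
#' the first record so output is deterministic. An empty list writes a
#' header-only file when `columns` is given, else an empty file.
#'
#' @param records list of named lists/vectors with identical names.
#' @param path output CSV path.
#' @param columns column names to use for an empty `records` list.
#' @export
write_results_table <- function(records, path, columns = NULL) {
  if (length(records) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(columns), logical(0), simplify = FALSE),
      columns))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  keys <- names(records[[1L]])
  if (is.null(keys) || any(!nzchar(keys)))
    stop("records must be fully named")
  for (i in seq_along(records)) {
    if (!setequal(names(records[[i]]), keys))
      stop("record ", i, " has different keys than record 1")
  }
  df <- do.call(rbind, lapply(records, function(r)
    as.data.frame(as.list(r[keys]), stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
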