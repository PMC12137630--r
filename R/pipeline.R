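#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages `simulate` (synthetic recording with ground
#' truth), `normalize` (dF/F), `detect` (population events),
#' `metrics` (pairwise correlations vs distance) and `decode`
#' (condition decoding on a simulated multi-animal experiment) over one
#' run directory. Each stage reads its predecessors' outputs from disk,
#' so stages can be re-run selectively; missing dependencies raise an
#' error naming the stage. A run manifest (config snapshot, package
#' version, seed, per-stage timings, md5 of every output file) is
#' written last; re-running with the same config and seed reproduces
#' bit-identical outputs.
#'
#' All randomness derives from the single `seed` via per-stage
#' substreams.
#'
#' @param out_dir run directory (created if needed).
#' @param config an [default_config()]-style list.
#' @param sim_overrides named arguments overriding [sim_config()]
#'   defaults for the simulate stage.
#' @param stages ordered subset of
#'   `c("simulate", "normalize", "detect", "metrics", "decode")`.
#' @param seed master seed (defaults to `config$seed`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = default_config(),
                         sim_overrides = list(),
                         stages = c("simulate", "normalize", "detect",
                                    "metrics"),
                         seed = NULL) {
  validate_config(config)
  seed <- as.integer(seed %||% config$seed)
  all_stages <- c("simulate", "normalize", "detect", "metrics", "decode")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(simulate = character(), normalize = "traces.csv",
               detect = "dff.csv", metrics = "dff.csv",
               decode = character())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  timings <- list()
  outputs <- character()

  for (st in all_stages[all_stages %in% stages]) {
    for (d in deps[[st]]) {
      if (!file.exists(p(d)))
        stop("stage '", st, "' needs ", d,
             " — run its predecessor stage first")
    }
    t0 <- proc.time()[["elapsed"]]
    new <- switch(st,
      simulate = {
        sc <- do.call(sim_config,
                      utils::modifyList(list(seed = seed), sim_overrides))
        sim <- simulate_recording(sc)
        write_recording(sim$recording, p("traces.csv"))
        write_recording(sim$red, p("red_traces.csv"))
        jsonlite::write_json(
          list(events = sim$truth$events,
               interneurons = sim$truth$interneurons,
               participants = lapply(sim$truth$participants, as.integer)),
          p("ground_truth.json"), digits = NA)
        c("traces.csv", "traces_coords.csv", "traces_meta.yaml",
          "red_traces.csv", "red_traces_coords.csv",
          "red_traces_meta.yaml", "ground_truth.json")
      },
      normalize = {
        rec <- read_recording(p("traces.csv"))
        dff <- if (config$normalization$method == "percentile")
          dff_percentile(rec, config$normalization$percentile)
        else dff_mean_baseline(rec)
        data.table::fwrite(data.table::as.data.table(dff$dff), p("dff.csv"),
                           col.names = FALSE)
        "dff.csv"
      },
      detect = {
        dff <- read_dff(out_dir)
        ev <- detect_events(dff, config$events$bin_s,
                            config$events$method,
                            config$events$h_threshold,
                            config$events$l_threshold,
                            config$events$min_duration_s)
        utils::write.csv(as.data.frame(ev), p("events.csv"),
                         row.names = FALSE)
        utils::write.csv(
          summarize_events(ev, ncol(dff$dff) / dff$frame_rate),
          p("event_summary.csv"), row.names = FALSE)
        c("events.csv", "event_summary.csv")
      },
      metrics = {
        dff <- read_dff(out_dir)
        corr <- suppressMessages(pairwise_correlations(dff))
        cvd <- correlation_vs_distance(corr, dff$coords,
                                       config$metrics$distance_bin_um)
        utils::write.csv(cvd, p("correlation_vs_distance.csv"),
                         row.names = FALSE)
        "correlation_vs_distance.csv"
      },
      decode = {
        tensor <- simulate_condition_experiment(
          effect = 2, seed = substream_seed(seed, "decode_stage"))
        res <- decode_condition(tensor, n_cells = 20L,
                                n_perm = config$decoding$n_perm,
                                alpha = config$decoding$alpha,
                                lambda = config$decoding$lambda,
                                seed = seed)
        utils::write.csv(
          data.frame(max_accuracy = res$observed$max_accuracy,
                     threshold = res$threshold, margin = res$margin,
                     significant = res$significant),
          p("decode_results.csv"), row.names = FALSE)
        "decode_results.csv"
      })
    timings[[st]] <- round(proc.time()[["elapsed"]] - t0, 3)
    outputs <- union(outputs, new)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neodev")),
    seed = seed,
    stages = stages,
    config = config,
    sim_overrides = sim_overrides,
    timings_s = timings,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_dff <- function(out_dir) {
  path <- file.path(out_dir, "dff.csv")
  if (!file.exists(path)) stop("no dff.csv in ", out_dir)
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  rec <- read_recording(file.path(out_dir, "traces.csv"))
  structure(list(dff = m, coords = rec$coords,
                 frame_rate = rec$frame_rate,
                 provenance = list(method = "from_disk")),
            class = "dff_recording")
}

#' Re-run a pipeline from its manifest and verify reproducibility
#'
#' Reads `manifest.json` from a finished run, re-executes the same stages
#' with the same config and seed into a scratch directory, and compares
#' output hashes.
#'
#' @param run_dir directory containing `manifest.json`.
#' @param rerun_dir directory for the re-run (default a tempdir).
#' @return list: `identical` (logical), `mismatched` file names.
#' @export
rerun_from_manifest <- function(run_dir, rerun_dir = tempfile("rerun")) {
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- modify_list_deep(default_config(), man$config)
  man2 <- run_pipeline(rerun_dir, cfg,
                       sim_overrides = as.list(man$sim_overrides),
                       stages = man$stages, seed = man$seed)
  h1 <- unlist(man$outputs)
  h2 <- unlist(man2$outputs)
  common <- intersect(names(h1), names(h2))
  bad <- common[h1[common] != h2[common]]
  list(identical = length(bad) == 0L && setequal(names(h1), names(h2)),
       mismatched = bad)
}
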