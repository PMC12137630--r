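#!/usr/bin/env Rscript
# Stage 1: generate the synthetic data set every later stage analyses —
# a 10 min baseline recording (200 cells at 30 Hz, planted H/L events),
# the red interneuron channel, a pose-tracking session and a serotonin
# trace. Everything is reproducible from the one seed below.

suppressPackageStartupMessages(library(neodev))
seed <- 1L
out <- "results/session01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

run_pipeline(out, sim_overrides = list(), stages = "simulate", seed = seed)

cfg <- sim_config(seed = seed)
plan <- data.frame(state = c("wake", "QS", "AS", "QS", "wake", "AS"),
                   duration_s = c(60, 120, 100, 120, 60, 140))
mv <- simulate_movement(cfg, plan)
write.csv(mv$pose, file.path(out, "pose.csv"), row.names = FALSE)
write.csv(data.frame(frame = seq_along(mv$truth$states) - 1L,
                     state = mv$truth$states),
          file.path(out, "state_truth.csv"), row.names = FALSE)
sero <- simulate_serotonin(cfg, mv$truth$states)
write.csv(data.frame(frame = seq_along(sero) - 1L, dff = sero),
          file.path(out, "serotonin.csv"), row.names = FALSE)

truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("simulated %d planted events (%s), %d interneurons, %d s of behaviour\n",
            nrow(truth$events),
            paste(names(table(truth$events$class)),
                  table(truth$events$class), collapse = " "),
            length(truth$interneurons), sum(plan$duration_s)))
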