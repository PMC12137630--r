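#!/usr/bin/env Rscript
# Stage 2: first-percentile dF/F normalisation and H-/L-event detection
# on the baseline recording, plus recovery against the planted truth.

suppressPackageStartupMessages(library(neodev))
out <- "results/session01"

run_pipeline(out, stages = c("normalize", "detect"), seed = 1L)
ev <- read.csv(file.path(out, "events.csv"))
summ <- read.csv(file.path(out, "event_summary.csv"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                             simplifyVector = TRUE)

mt <- match_events(ev, truth$events, frame_rate = 30)
write.csv(mt, file.path(out, "event_recovery.csv"), row.names = FALSE)
cat(sprintf("detected %d events (planted %d): %.0f%% recovered, mean participation error %.2f points\n",
            nrow(ev), nrow(truth$events), 100 * mean(mt$detected),
            100 * mean(abs(mt$participation_detected -
                             mt$participation), na.rm = TRUE)))
print(summ, row.names = FALSE)
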