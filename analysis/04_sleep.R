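#!/usr/bin/env Rscript
# Stage 4: movement extraction from pose tracking, wake/QS/AS scoring,
# and state-conditioning of the serotonin trace (expected ordering:
# wake > QS > AS).

suppressPackageStartupMessages(library(neodev))
out <- "results/session01"

pose <- read.csv(file.path(out, "pose.csv"))
move <- movement_from_pose(pose)
bouts <- score_sleep_states(move)
write.csv(as.data.frame(bouts), file.path(out, "sleep_bouts.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(out, "state_truth.csv"))$state
st <- attr(bouts, "states")
truth <- truth[seq_along(st)]
cat(sprintf("scored %d bouts; frame accuracy %.3f, AS recall %.3f\n",
            nrow(bouts), mean(st == truth),
            mean(st[truth == "AS"] == "AS")))

sero <- read.csv(file.path(out, "serotonin.csv"))$dff
sc <- state_conditioned_signal(sero, bouts)
write.csv(sc, file.path(out, "serotonin_by_state.csv"), row.names = FALSE)
print(sc, row.names = FALSE)
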