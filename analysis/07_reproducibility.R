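#!/usr/bin/env Rscript
# Stage 7: determinism audit — run the full pipeline into a fresh
# directory, re-run it from the recorded manifest, and compare output
# hashes.

suppressPackageStartupMessages(library(neodev))
out <- "results/repro_run"
unlink(out, recursive = TRUE)
run_pipeline(out, sim_overrides = list(n_cells = 40, duration_s = 120),
             seed = 1L)
chk <- rerun_from_manifest(out)
cat(sprintf("manifest re-run identical: %s\n", chk$identical))
if (length(chk$mismatched))
  cat("mismatched files:", paste(chk$mismatched, collapse = ", "), "\n")
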