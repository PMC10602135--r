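#!/usr/bin/env Rscript
# Simulate a study-sized synthetic cohort (31 annotated robotic
# proctectomies) from the default workflow model and write its annotation
# files under results/cohort/. Everything downstream (02, 03) reads these
# files, never the model, so the pipeline exercises the same I/O path a
# clinical annotation export would.

library(procflow)

cfg <- run_config(out = "results/cohort", n = 31, seed = 7)
res <- run_simulate(cfg)
coh <- res$cohort

cat("Simulated", n_procedures(coh), "procedures,", nrow(coh$events),
    "step visits in total\n")
cat(sprintf("Visits per procedure: mean %.1f, range %d-%d\n",
            nrow(coh$events) / n_procedures(coh),
            min(table(coh$events$procedure_id)),
            max(table(coh$events$procedure_id))))
cat(sprintf("Console time: mean %.0f min; total operative time: mean %.0f min\n",
            mean(coh$metadata$console_time_min),
            mean(coh$metadata$total_operative_time_min)))
cat("Files:", paste(res$paths, collapse = ", "), "\n")
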