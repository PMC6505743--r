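#!/usr/bin/env Rscript

# Stage 1 — simulate the two-arm synthetic HDU cohort.
#
# Generates the study-calibrated cohort (300 patients per arm by default:
# large enough for parameter-recovery checks, small enough to run in
# seconds), splits it by arm, and writes the on-disk dataset for the audit
# stage under results/sim/.

suppressPackageStartupMessages(library(mewsaudit))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20130601
out_root <- "results/sim"

cfg <- paper_like_config(n_per_arm = 300, seed = seed)
cohort <- run_simulate(cfg, out_root)

# per-arm splits for the audit stage
for (arm in c("control", "intervention")) {
  dir <- file.path(out_root, arm)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recordings(cohort$recordings[cohort$recordings$period == arm, ],
                   file.path(dir, "recordings.csv"))
  write_stays(cohort$stays[cohort$stays$arm == arm, ],
              file.path(dir, "stays.csv"))
}

ev <- cohort$truth$events
cat(sprintf("\nSimulated %d patients, %d intended assessment events.\n",
            nrow(cohort$stays), nrow(ev)))
cat(sprintf("True MEWS >= 3 at %.1f%% of events (deterioration episodes).\n",
            100 * mean(ev$true_mews >= 3)))
cat(sprintf("Configured compliance: control %.1f%%, intervention %.1f%%.\n",
            100 * cfg$compliance[["control"]],
            100 * cfg$compliance[["intervention"]]))
cat("Dataset written under", out_root, "\n")
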