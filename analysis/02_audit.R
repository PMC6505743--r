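#!/usr/bin/env Rscript

# Stage 2 — build assessments and audit protocol adherence, per arm.
#
# Reads the simulated recordings, groups them with the 15-minute rule,
# recomputes every MEWS, audits each stay against the response protocol
# (terminal assessments excluded from the denominator), and writes
# assessments/audit/strata tables under results/audit/<arm>/.

suppressPackageStartupMessages(library(mewsaudit))

for (arm in c("control", "intervention")) {
  in_dir <- file.path("results/sim", arm)
  out_dir <- file.path("results/audit", arm)
  res <- run_audit(file.path(in_dir, "recordings.csv"),
                   file.path(in_dir, "stays.csv"),
                   out_dir)
  cc <- completeness_counts(res$assessments)
  cat(sprintf(
    "%s arm: %d assessments, %d complete (%.1f%%), adherence %.1f%%\n",
    arm, cc[["n_total"]], cc[["n_complete"]],
    percent_from_counts(cc[["n_complete"]], cc[["n_total"]]),
    100 * adherence_rate(res$verdicts)))
}
cat("Audited datasets written under results/audit/\n")
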