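#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 26 active / 27 placebo subjects, two
# visits, with the study's effects injected at follow-up in the active group
# (reduced loss outcome sensitivity; start point shifted toward the no-go
# boundary under aversive interference). Writes the trial and outcome tables
# under results/cohort/.

suppressMessages(library(serocog))

spec <- cohort_spec(seed = 20260101)
cohort <- simulate_cohort(spec)
paths <- write_cohort(cohort, "results/cohort")

cat("Simulated", nrow(cohort$truth), "subjects (",
    sum(cohort$truth$group == "active"), "active /",
    sum(cohort$truth$group == "placebo"), "placebo )\n")
cat("PILT trials:", nrow(cohort$pilt), " GNG trials:", nrow(cohort$gng), "\n")
cat("Summary outcome rows:", nrow(cohort$outcomes),
    " daily rating rows:", nrow(cohort$daily), "\n")
cat("Tables written:\n")
for (p in paths) cat("  ", p, "\n")
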