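#!/usr/bin/env Rscript
# Behavioural summaries per subject, visit and condition: optimal-choice
# percentages and response times for the learning task; response
# inhibition, go accuracy, go RT and signal-detection indices (d', c) for
# the go/no-go task. Writes results/behavioural_summaries.csv.

suppressMessages(library(serocog))

pilt <- read_trial_table("results/cohort/pilt.csv")
gng <- read_trial_table("results/cohort/gng.csv")

summaries <- rbind(summarise_pilt(pilt), summarise_gng(gng))
write.csv(summaries, "results/behavioural_summaries.csv", row.names = FALSE)

show <- function(nm, cond, visit = "followup") {
  v <- summaries$value[summaries$outcome == nm &
                         summaries$condition == cond &
                         summaries$visit == visit]
  sprintf("%.1f", mean(v))
}
cat("Follow-up means across subjects:\n")
cat("  optimal choice % (win):", show("optimal_choice", "win"),
    " (loss):", show("optimal_choice", "loss"), "\n")
cat("  response inhibition % (control):",
    show("response_inhibition", "control"),
    " (aversive):", show("response_inhibition", "aversive"), "\n")
cat("  correct-go RT ms (control):", show("go_rt", "control"),
    " (aversive):", show("go_rt", "aversive"), "\n")
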