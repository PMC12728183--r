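#!/usr/bin/env Rscript

# The preregistered analysis: subset each condition's 12 test rounds and
# regress the binary cue-following indicator on historical predictivity
# (linear probability model, participant-clustered CR1 standard errors).
# Writes the coefficient table and the per-10-percentage-point marginal
# effects.
#
# Usage: Rscript analysis/02_analyze.R [in_csv]

suppressPackageStartupMessages(library(lenscue))

args <- commandArgs(trailingOnly = TRUE)
infile <- if (length(args) >= 1) args[1] else "results/simulated_choices.csv"
dir.create("results", showWarnings = FALSE)

d <- read_study_data(infile)
tab <- regression_table(d)
readr::write_csv(tab, "results/regression_table.csv")

writeLines(format_regression_table(tab))
writeLines(format_regression_table(tab), "results/regression_table.txt")

me <- vapply(tab$condition, function(cc) {
  marginal_effect(preregistered_regression(d, cc), delta = 0.10)
}, numeric(1))
cat("\nEstimated increase in cue-following per +10 points of historical predictivity:\n")
cat(sprintf("  %-8s %+.2f percentage points\n", tab$condition, me), sep = "")
cat("\nwrote results/regression_table.{csv,txt}\n")
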