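#!/usr/bin/env Rscript

# Simulate one full study: 300 probability-matching participants per cue
# condition, each with an assigned predictivity drawn uniformly on [0, 1],
# running through 3 practice + 28 treatment + 12 test rounds. Writes the
# long-format choice dataset consumed by 02_analyze.R.
#
# Usage: Rscript analysis/01_simulate.R [seed] [n_per_condition]

suppressPackageStartupMessages(library(lenscue))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
n_per <- if (length(args) >= 2) as.integer(args[2]) else 300L
dir.create("results", showWarnings = FALSE)

cat(sprintf("Simulating %d matching-learner participants per condition (seed %d)...\n",
            n_per, seed))
d <- simulate_study(n_per, agent_params("matching_learner"), seed = seed)
out <- "results/simulated_choices.csv"
write_choice_data(d, out)

cat(sprintf("  %d choice records from %d participants -> %s\n",
            nrow(d), length(unique(d$participant_id)), out))
tst <- d[d$round_kind == "test", ]
cat(sprintf("  test-round cue-following rate: %.3f (chance benchmarks: decoy 1/2 if dominance-respecting, else 1/3)\n",
            mean(tst$chose_cue_option)))
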