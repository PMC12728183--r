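#!/usr/bin/env Rscript

# Binned local averages of cue-following by historical predictivity
# (rounded to two decimals), with the analytic chance benchmarks, plus a
# figure if ggplot2 is available. A regression that tracks adaptation to
# the cue should cross its chance line where historical predictivity
# equals the chance rate of the cue landing on the superior option.
#
# Usage: Rscript analysis/03_report.R [in_csv]

suppressPackageStartupMessages(library(lenscue))

args <- commandArgs(trailingOnly = TRUE)
infile <- if (length(args) >= 1) args[1] else "results/simulated_choices.csv"
dir.create("results", showWarnings = FALSE)

d <- read_study_data(infile)
b <- binned_choice_rates(d)
readr::write_csv(b, "results/binned_rates.csv")
cat(sprintf("wrote results/binned_rates.csv (%d bins)\n", nrow(b)))

bench <- data.frame(
  condition = rep(c("decoy", "default", "rule"), each = 2),
  assumption = rep(c("uniform_over_3", "dominance_respecting"), 3)
)
bench$benchmark <- mapply(chance_benchmark, bench$condition, bench$assumption)
readr::write_csv(bench, "results/chance_benchmarks.csv")
cat("chance benchmarks:\n")
print(bench, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(b[b$n >= 5, ], aes(predictivity_bin, choice_rate)) +
    geom_point(aes(size = n), alpha = 0.5) +
    geom_smooth(method = "lm", se = FALSE, linewidth = 0.6,
                show.legend = FALSE, aes(weight = n)) +
    geom_hline(data = bench[bench$assumption == "uniform_over_3", ],
               aes(yintercept = benchmark), linetype = "dashed") +
    facet_wrap(~condition) +
    labs(x = "historical predictivity (binned to 2 dp)",
         y = "share choosing the cue-indicated option",
         size = "observations") +
    theme_minimal()
  ggsave("results/binned_rates.png", p, width = 9, height = 3.5, dpi = 150)
  cat("wrote results/binned_rates.png\n")
}
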