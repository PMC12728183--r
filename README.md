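# lenscue

Simulation and analysis of choice experiments in which an experimental
manipulation doubles as a *probabilistic cue*.

Many classic behavioural manipulations — adding a dominated decoy to an
option set, pre-selecting a default, marking options with a visual
feature — change a stimulus characteristic. If that characteristic is
statistically associated with which option pays best, it becomes a cue
in the Brunswikian lens-model sense, and participants may calibrate how
much they rely on it to how well it has predicted the best option so
far. `lenscue` implements that ecology as a stochastic simulator,
provides synthetic choice agents as stand-ins for participants, and
ships the preregistered-style analysis that estimates the resulting cue
weight. It is aimed at decision scientists who want to study, power, or
stress-test designs of this kind before (or instead of) collecting
human data.

## The design being simulated

Each synthetic participant is assigned one of three cue conditions and
an *assigned predictivity* `p`:

* **decoy** — one option has a same-shaped, dominated decoy (smaller
  area *and* higher price);
* **default** — one option is pre-selected;
* **rule** — one option bears the participant's indicator shape.

A session has 3 practice + 28 treatment + 12 test rounds; treatment and
test rounds are interleaved in random order. Every round shows three
options (area, price), the payoff being area − price. Three payoffs are
drawn from a normal distribution and ranked, prices drawn from another
normal, areas set to payoff + price. On treatment rounds the cue lands
on the superior option with probability `p`; on test rounds its
placement is at chance (1/2 for the decoy's two non-dominated hosts,
uniform over the three options for default and rule), so test rounds
are identically distributed for everyone.

Per round, the cue-predictive dummy is

    cue_predictive_r = 1  iff the cue-indicated option is the superior option,

and the running experience of the participant is the *historical
predictivity*

    historical_predictivity_r = sum_{i<r} cue_predictive_i / (r - 1).

The preregistered analysis subsets the 12 test rounds per condition and
fits the linear probability model

    chose_cue_option ~ historical_predictivity

by OLS with participant-clustered (CR1) standard errors. The slope is
the estimated **cue weight**: the change in the probability of choosing
the cue-indicated option per unit of historical predictivity.

## Worked example

```r
library(lenscue)

# one option as displayed on the task screen
option_spec(area = 183, price = 53)$payoff
#> [1] 130

# a full study of probability-matching agents and its analysis
d <- simulate_study(300, agent_params("matching_learner"), seed = 1)
writeLines(format_regression_table(regression_table(d)))
```

```
Test-round linear probability models (one per condition)
Dependent variable: cue-indicated option was chosen
condition    constant         (se)      slope         (se)        n  clusters
decoy           0.320      (0.018)      0.698      (0.029)     3600       300
default         0.326      (0.014)      0.682      (0.023)     3600       300
rule            0.339      (0.016)      0.653      (0.026)     3600       300
```

A probability-matching agent follows the cue with probability equal to
its experienced predictivity `h` and otherwise chooses at random, so its
true choice rate is `1/3 + (2/3) h`: the fitted slopes sit near 2/3 and
the intercepts near 1/3, and a +10-percentage-point increase in
historical predictivity raises cue-following by about 6.5–7 percentage
points. The same pipeline runs unchanged on externally deposited
datasets through a [`column_map()`](R/io.R) (see `read_study_data()`).

The `analysis/` scripts chain these steps from the shell:

```sh
Rscript analysis/01_simulate.R 1 300   # -> results/simulated_choices.csv
Rscript analysis/02_analyze.R          # -> results/regression_table.{csv,txt}
Rscript analysis/03_report.R           # -> binned rates, chance benchmarks, figure
```

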