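---
title: "Simulating cue-predictivity experiments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cue-predictivity experiments: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenscue)
```

# The ecology

`lenscue` simulates a three-alternative incentivised choice task in
which an experimental manipulation — a dominated decoy, a pre-selected
default, or an indicator shape — is also a probabilistic cue for the
highest-payoff option. The lens-model reading is that the manipulation
creates a proximal cue whose ecological validity (*cue predictivity*)
the participant can learn from feedback; the analysis estimates the
behavioural *cue weight* as the slope of cue-following on experienced
predictivity.

Each round offers three geometric options with a displayed area and
price; choosing yields payoff = area − price, and full feedback reveals
all payoffs. Three payoffs are drawn from one normal distribution and
ranked; prices come from a second normal; areas are set to
payoff + price, so the payoff identity holds by construction. A session
is 3 practice rounds followed by 28 treatment and 12 test rounds in
uniformly random interleaved order.

Cue placement:

* *treatment rounds* — with probability `p` (the participant's assigned
  predictivity) the cue marks the superior option. Otherwise, in the
  decoy condition the second-best option has the decoy (with the worst
  option as its decoy); in the default and rule conditions one of the
  two inferior options is marked, chosen uniformly.
* *test rounds* — decoy: the superior or second-best option hosts the
  decoy with probability 1/2 each and the worst option is the decoy;
  default and rule: the marked option is uniform over all three. Test
  rounds are thus uninformative in expectation and identically
  distributed across participants of a condition.

The decoy is built from the host (target) option by drawing a
proportion `q ~ U[0, 1]` of the target–source payoff difference: `q` of
the difference is added to the target's price to give the decoy price,
and the remaining `1 − q` subtracted from the target's area to give the
decoy area. The decoy keeps the source's payoff exactly and is
dominated by the target in both attributes (strictly for interior `q`;
at the endpoints dominance is weak in one attribute, a probability-zero
event under the continuous sampler). The decoy takes the target's
shape, making the area comparison within the pair easy.

# Statistics

Per round, `cue_predictive` is 1 iff the cue-indicated option is the
superior option. The running mean of these flags over rounds
`1 .. r-1` is the *historical predictivity* at round `r`; it is
undefined at `r = 1` and, since three practice rounds precede every
experiment round, always defined where the analysis uses it. Practice
rounds count towards the history by default
(`include_practice_in_history` toggles this for sensitivity analyses).

The preregistered-style analysis subsets each condition's 12 test
rounds and fits, by OLS, the linear probability model

\[
\Pr(\text{chose cue option}) = \beta_0 + \beta_1 \,\text{historical predictivity},
\]

with cluster-robust standard errors at the participant level. The CR1
small-sample scaling \(\frac{G}{G-1}\frac{n-1}{n-k}\) is used (the
common econometric default; immaterial at hundreds of clusters), with
t inference on \(G - 1\) degrees of freedom. A random-effects variant
is deliberately out of scope; the clustered OLS is the primary
specification. `marginal_effect()` re-expresses the slope in
percentage points of choice probability per `delta` change in
predictivity. `binned_choice_rates()` reproduces the standard
visualisation: observations grouped by historical predictivity rounded
to two decimals, each bin a local average.

Chance benchmarks for test rounds come in two analytic flavours: a
uniform chooser selects the cue option with probability 1/3 in every
condition; a dominance-respecting chooser (one that never picks the
dominated decoy) selects it with probability 1/2 in decoy test rounds —
the cue is equally likely on either of the two non-dominated options —
and 1/3 elsewhere. Both are implemented; which one a given dataset
should be compared against depends on the behavioural assumption one is
willing to make, so neither is privileged.

# Generator parameters and defaults

The magnitudes of the payoff and price distributions are calibrated to
the task's display scale (an example screen shows area 183, price 53,
payoff 130):

| parameter | default | units | rationale |
|---|---|---|---|
| payoff mean, sd | 130, 30 | currency units | matches displayed payoff magnitudes |
| price mean, sd | 55, 15 | currency units | matches displayed prices; keeps areas positive |
| truncation | at 1 | — | areas and prices must be positive; ~4 sd from the means, so practically inert |
| rounding | integers | — | displayed arithmetic is exact (183 − 53 = 130) |
| assigned predictivity | U(0, 1) | probability | maximum-entropy default; configurable per study |
| rounds | 3 + 28 + 12 | — | the emulated session structure |

Payoffs and prices are drawn from the truncated normals by inverse-CDF
sampling and rounded to whole units *before* ranking; payoffs are
computed on the rounded values so the identity is exact in display
units. Decoy adjustments are left continuous: rounding them would break
exact payoff conservation, and strict dominance for interior `q` would
otherwise fail when the rounded transfer collapses to zero.

Numerical and degenerate-input choices:

* rounded payoff ties would make "the superior option" ill-defined, so
  tied rounds are redrawn (bounded retries; a degenerate distribution
  such as `payoff_sd = 0` raises an error);
* perceived-payoff ties in the attribute policy break towards the
  earliest screen position (left, middle, right) — a documented,
  deterministic tie-break;
* the matching learner's empty history uses the chance rate 1/3, the
  uninformed prior over three options;
* the regression refuses fewer than two clusters or zero variance in
  historical predictivity, and flags (rather than hides) the degenerate
  zero-residual case;
* in the `1 − p` branch of default and rule treatment rounds the marked
  inferior option is chosen uniformly between the two — the
  maximum-entropy reading of "one of the two inferior options";
* shapes of the non-decoy options are drawn independently, so a
  coincidental shared shape is allowed (only the target–decoy pair is
  constrained to share one, and the indicator shape appears exactly
  once per round in the rule condition).

# Synthetic agents

Human participants are replaced by choice policies chosen to span the
behaviours such tasks are discussed in terms of:

* `random` — uniform over positions; the null model for calibration;
* `attribute` — an "intuitive statistician" maximising perceived
  payoff. Perceptual noise is multiplicative on area only
  (`area * (1 + eps)`, `eps ~ N(0, sd)`): areas are judged visually
  while prices are printed numerals;
* `cue_hybrid` — follows the cue with probability `w`, else falls back
  to `random` or `attribute`. With an intercept, the cue-response is
  affine in the experienced predictivity, `P(follow | h) = w0 + w1 h`,
  which gives closed-form recovery targets;
* `matching_learner` — probability matching: `w = h`, random fallback.

Because feedback reveals the superior option every round regardless of
the choice made, the history an agent conditions on is the round
sequence's own cue-predictive flags; choices at round `r` therefore
depend only on rounds before `r` (non-anticipation), and the running
predictivity can be computed up front without changing the online
semantics.

For an agent with cue-following probability `v(h)` and uniform
fallback, the probability of choosing the cue option is
`v + (1 − v)/3 = 1/3 + (2/3) v`. An affine responder with slope `w1`
therefore induces a test-round regression slope of `(2/3) w1` and a
matching learner a slope near 2/3 with intercept near 1/3 — the oracle
values used by the recovery checks.

What the agents do *not* model: reaction times, learning dynamics other
than the running average, asymmetries between cue types, or any claim
about the cognitive mechanism behind human cue use. Passing recovery
tests shows the pipeline estimates what the generator encodes, not that
human data follow these policies.

# Problem sizes used by the checks

The packaged checks run at sizes chosen to give tight Monte-Carlo
bands while staying desk-scale: ~10,000 generated decoy rounds for the
construction invariants; ~20,000 test rounds per condition against
exact binomial 99% bands for the chance rates; studies of 300
participants per condition (the emulated study's scale) for cue-weight
recovery; and 500 studies of 100 cue-blind participants for the size of
the slope test, compared against a binomial 95% band around the nominal
0.05.

# Known limitations

* The payoff/price distribution parameters and the distribution of
  assigned predictivity are package defaults calibrated to the display
  magnitudes, not measured quantities; studies with other stakes should
  set them explicitly.
* The linear probability model is linear by design; with cue-following
  rates near 0 or 1 its predictions can leave \[0, 1\], which is
  inherent to the specification, not a bug.
* Session delivery details (response timers, comprehension checks,
  payment conversion) are out of scope; the 1500-units-per-GBP exchange
  rate of the emulated task is metadata only.
* Reading externally deposited data requires a `column_map()` matched
  to the deposit's actual schema; the package ships only an identity
  default.
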