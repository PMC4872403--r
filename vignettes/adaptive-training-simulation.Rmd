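---
title: "Simulating adaptive signal-to-noise training trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating adaptive signal-to-noise training trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrain)
library(dplyr)
```

adaptrain simulates a performance-adaptive cognitive training program for
children with ADHD together with the randomized controlled trial that
evaluates it. Everything is generated in silico: the adaptive exercises, the
virtual subjects who play them, the clinical and cognitive assessment
battery, and the statistical analysis of the resulting dataset. The point of
the package is that the *design* — staircase control, curriculum structure,
blocked randomization, assessment schedule, and the complete nonparametric
analysis plan — can be exercised, validated and reused without any clinical
data. This vignette explains the models, the tunable parameters, the
numerical choices, and what the simulations can and cannot tell you.

## The adaptive staircase

Every training exercise adjusts its difficulty with a transformed up-down
(3-down-1-up) staircase on a normalized challenge axis $c \in [0, 1]$:
three consecutive correct responses raise $c$ by the current step and reset
the counter, any error lowers $c$ immediately, and each reversal of
direction halves the step down to a floor. The rule equilibrates where the
probability of three consecutive correct responses equals one half, i.e. at
$p = 0.5^{1/3} \approx 0.794$ — inside the 75–85% percent-correct band the
training is designed to hold, a level challenging but not frustrating.

The staircase flavor itself is a design choice: the program only commits to
"staircase control into a 75–85% band", and the 3-down-1-up rule is the
standard psychophysical procedure whose theoretical convergence point sits
inside that band. Step-size parameters are likewise design choices: an
initial step of 0.08 on the unit axis approaches threshold quickly, halving
at each reversal down to a floor of 0.01 gives stable tracking, and an
initial challenge of 0.1 reflects the program's easy start. Challenge maps
to physical stimulus dimensions per exercise category: attended-signal
exercises reduce target salience as $1 - c$, distractor exercises raise
distractor-to-target similarity as $c$, and the response-inhibition
exercise shortens the interstimulus interval linearly from 3 s down to
0.5 s.

```{r staircase}
sim <- simulate_staircase(logistic_observer(), n_trials = 2000, seed = 1)
glance(sim)
```

Steady-state behavior is summarised after a burn-in of the first 200 trials
or the first six reversals, whichever ends later; before that point the
staircase is still descending from its easy start and would bias the
accuracy estimate upward. `autoplot()` on the result shows the trajectory.

Whether staircase memory persists across sessions is not specified by the
program description; the engine persists the converged challenge across
sessions of the same exercise and resets the step size each session, so
returning subjects re-approach threshold quickly without losing their
level. This is a default, not an assertion about the original
implementation.

## The exercise registry and the curriculum

`build_registry()` constructs the 25 exercises: eight attended-signal,
eight explicit-distractor and eight implicit-distractor modules — four
visual and four auditory each, climbing a four-tier complexity ladder
(Gabor patches, shapes/textures, motion, scenes; tones, sweeps, phonemes,
words) — plus a single visual go/no-go response-inhibition exercise. The
go/no-go exercise forms a one-exercise chain and is available from the
start; the tier ladders govern the other 24.

Sessions are scheduled by `schedule_session()`: up to seven exercises of
3–5 minutes within a 30-minute window, least-trained first, and a tier-k
exercise unveils only after the tier-(k−1) exercise of the same category and
modality is completed. Three defaults deserve mention because the program
description leaves them open. First, visual and auditory chains unveil
independently. Second, an exercise counts as "completed" for unveiling after
60 cumulative training minutes — with 25 exercises and a 30-hour curriculum
(72 minutes per exercise on average) this unlocks the full ladder roughly
halfway through training. Third, each block presents 40 trials, a typical
count for a 3–5 minute adaptive block. Compliance bookkeeping counts the
30-minute session window, so the assigned dose of 60 sessions is exactly
30 hours.

## Virtual subjects

Each subject carries three latent traits on the challenge axis —
`signal_sensitivity`, `distractor_suppression`, `inhibition` — drawn from a
Beta(2.5, 4.5) (mean ≈ 0.36, reflecting impaired baseline ability relative
to the mid-axis), a lapse rate uniform on [0, 0.06], and responds to a trial
at challenge $c$ with probability

$$P(\text{correct}) = \gamma + (1 - \gamma - \lambda)\,
  F\!\left(\frac{\text{trait} - c}{\sigma}\right),$$

a lapse-corrected logistic observer with guess floor $\gamma$ (0.5 for
two-alternative forced choice, 0 for go/no-go), lapse $\lambda$ and scale
$\sigma = 0.125$. The observer model is a package choice — the original
study had real children — selected because it is the standard psychometric
form and every downstream property can be checked against its closed form.

Training moves the traits with a saturating update: each session adds
`rate × minutes × (1 − trait)` to each trained trait, which iterates to the
closed form $1 - (1 - t_0)(1 - rm)^k$ after $k$ sessions. The base rate is
4 × 10⁻⁴ per trained minute, and each subject carries independent per-trait
log-normal (sdlog 0.6) responsiveness multipliers. That heterogeneity is
deliberate: subjects differ substantially in how much they gain from
training, and it is this between-subject variation that produces a
correlation between trained distractor suppression and symptom improvement
at realistic strength, rather than a uniform shift everyone shares. The
multipliers are independent across traits, so improvements in attended-signal
ability do not automatically track symptom change — only the
distractor-suppression trait is coupled to symptoms.

Symptom severity is modeled on the 0–54 total of an 18-item, 0–3
parent-rating instrument:

$$\text{rating} = \mathrm{clamp}\big(\mathrm{round}(\,\text{intercept}
  - \beta \cdot \text{distractor\_suppression} + \varepsilon\,),\ 0,\ 54\big),$$

with per-subject intercepts Normal(43, 4), coupling $\beta = 30$ rating
points per unit trait, and rating noise sd 1.5 points. At baseline traits
this puts mean severity near 32; completing 30 hours of training moves the
distractor trait enough for a mean improvement of roughly 5–8 points. The
coupling strength is a free generator parameter — no clinical mapping
between distractor errors and rating points exists to anchor it — and
`coupling_strength = 0` with `learning_rate = 0` gives a null generator for
calibration studies. The control arm's games leave the traits unchanged by
default (`control_learning_rate` can model placebo drift). The clinician
severity impression is a coarsened 1–7 rendering of the same latent
severity.

## The assessment battery

* **Continuous performance test**: two 200-trial halves (10 minutes at 3 s
  per trial), targets on exactly 22.5% of trials in the sustained-attention
  half (45 of 200) and 77.5% in the response-inhibition half (155 of 200).
  Hits are driven by the signal trait, false alarms by the inhibition
  trait, both at a fixed assessment challenge of 0.2 (easier than the
  trained threshold region, as standardized clinical tests are). Scoring is
  $d' = z(\text{hit rate}) - z(\text{false-alarm rate})$ with the
  log-linear correction (add 0.5 to each count, 1 to each denominator) so
  perfect rates stay finite; the correction is smooth and has a testable
  closed form, unlike rate clamping.
* **Span tasks**: loads 1/3/5/7 (spatial) and 3/5/7/9 (verbal), 12 trials
  per load, half match probes — so the 50% match prevalence is exact by
  construction. Response time is `base + slope × load / (0.5 + trait)` plus
  noise; the metric is mean speed over the two highest loads. Accuracy is
  held stable across timepoints by construction, mirroring the test's use
  of speed as the only moving metric.
* **Stroop**: simulated at the sheet-count level (three 100-stimulus
  sheets, 45 s each), not per-stimulus reaction times. The interference
  score is color–word correct minus color correct; it is typically negative
  and improvement means less negative. That sign convention for
  "improvement" is adopted and documented here rather than asserted as the
  original coding.
* **Screening**: subtype cutoffs (> 2.11 combined, > 2.48 inattentive,
  > 2.00 hyperactive) are strict inequalities; a score exactly at cutoff is
  screen-negative.
* **Embedded distractor probe**: a fixed-challenge, non-adaptive 200-trial
  block (100 distractor trials) at the start and end of training. Its
  false-positive probability, `lapse + (1 − lapse)(1 − trait) × challenge`,
  falls linearly to exactly zero at the trait ceiling; the end-minus-start
  change in false positives is the quantity correlated with symptom change.

## The trial engine

`randomize_arms()` implements blocked 2:1 allocation in blocks of eight:
the per-block training count follows the cumulative target greedily
(alternating 5:3 and 6:2 for full blocks, a proportional split for the
final short block when n is not a multiple of eight — at n = 31 this
reproduces a 21:10 allocation), and medication status is balanced across
arms by tracking the medicated share cumulatively across blocks, with an
unstratified fallback (and warning) when a block is single-stratum.

Dropout (default 3/31) is drawn between baseline and intervention start —
dropouts retain baseline-only records — and mid-trial attrition is
expressed instead as partial compliance: roughly half of the retained
training arm trains only 1–13 hours (drawn around 4.5 ± 3.6 h). Ratings
occur at baseline, 3, 6 and 12 months; cognitive instruments at baseline
and post only; no intervention access exists between post and follow-up, so
follow-up traits equal post traits (sustained benefit is a model
assumption, not a finding). Arm labels never enter assessment computation —
assessments read only the subject's traits, and a blinding audit test
checks that identical-trait subjects in opposite arms produce identical
assessments under the same seed.

`run_trial()` offers three granularities: `"trial"` simulates every
adaptive trial through the staircases (full training logs), `"session"`
(default) drives learning through the scheduler at session resolution, and
`"aggregate"` bypasses the scheduler, splitting each session across
categories in registry proportion (8+8+8+1 of 25). The aggregate path is
the replicate-study engine: trait trajectories then follow the closed-form
recursion exactly, which is what makes 500-replicate calibration studies
cheap. Learning is identical in expectation across granularities; only log
resolution differs.

```{r trial}
cohort <- generate_cohort(cohort_config(), seed = 1)
dataset <- run_trial(cohort, seed = 1)
dataset
```

## The analysis plan

`analyze_trial()` reproduces the full plan on any schema-valid dataset:
between-group runs tests on rating change at each timepoint; within-group
Friedman ANOVAs over the four timepoints (completers, controls, partial
trainees; ratings and clinician severity); a Kruskal–Wallis test of
medication status against rating change; Wilcoxon matched-pairs tests of
baseline against every later timepoint; Levene variance checks followed by
the mixed-design ANOVA on the five cognitive change scores and per-test
pooled t-tests; bias-corrected effect sizes (Hedges' g) on rating change at
post and follow-up; and the Pearson correlation of embedded-probe
false-positive change against rating change in completers.

All nonparametric statistics are implemented from their defining formulas
with exact small-sample null distributions: the runs-test null from the
combinatorial run-count distribution (total n ≤ 12, normal approximation
with continuity correction otherwise), the Wilcoxon signed-rank null by
convolution over the observed (possibly tied) ranks on a doubled-integer
grid — exact under ties, unlike the textbook tables — for n ≤ 25, and the
Friedman null by exhaustive enumeration of within-block permutations for
nk ≤ 12 on tie-free data. The test suite verifies every exact path
bit-for-bit against independent brute-force enumeration, and the
large-sample paths against the base R implementations.

Several analysis conventions are deliberate choices on points the source
material leaves open:

* **Runs-test ties.** Integer rating scales guarantee cross-sample ties,
  which the classical test does not admit. Tied labels are interleaved
  alternately within each tied value (deterministic, with a warning). The
  obvious alternative — stable input order, one sample first — stacks tied
  labels on one side and manufactures separation: in a 500-replicate null
  calibration it inflated the between-group test's type-I error to 0.078,
  while the neutral interleaving policy is conservative (0.002).
* **Wilcoxon zeros** are dropped (the original convention), not Pratt-ranked.
* **Levene's test** centers on the group mean (the original form), not the
  median.
* **No multiple-testing correction** is applied by default, mirroring
  per-test reporting; `holm = TRUE` adds adjusted p-values.
* **Mixed ANOVA** refuses missing cells — the analysis is completer-only by
  design, with no imputation and no intent-to-treat reconstruction.
* The reported "training hours vs medication" association is computed as a
  point-biserial correlation and flagged `interpretation` in the report,
  because the statistic conventionally reported for that logistic fit is
  ambiguous.

## What the simulations do and do not show

The generator reproduces the *structure* of a small training trial — cohort
size 31, 2:1 blocked medication-stratified allocation, ~half medicated,
dropout and partial compliance at realistic rates, the exact assessment
prevalences and schedule — and couples exactly one mechanism (distractor
suppression) to the clinical outcome. Calibration studies in the test suite
show that under the null generator the headline tests keep their size
(rejection ≤ 0.07 at α = 0.05 over 500 replicates) and that under the
default effect generator the distractor-improvement/symptom-improvement
correlation is positive in far more than 95% of replicates, with the
within-group baseline-to-post test detecting the improvement in ≥ 90%.

What passing these does **not** show: that real children learn by a
saturating single-rate process, that symptom ratings are linear in any
latent trait, that rater expectations and placebo dynamics are ignorable
(the generator has no rater model), or that the published clinical effect
sizes are reproducible — real-cohort quantities depend on data that only
exists in the clinic. Simulated effect sizes here are generator properties,
not clinical estimates, and the default coupling was fixed from a design-time
power sketch, not fitted to any outcome.

Problem sizes used throughout the checks — 2000-trial staircase runs,
500-replicate null studies and 200-replicate effect studies on the
aggregate engine, exhaustive enumeration up to 12 observations — are the
package's chosen validation scale: large enough for the Monte-Carlo bounds
asserted, small enough to run routinely.

## Reproducibility

Every public function that draws random numbers takes a `seed`;
`run_trial()` derives a named substream per stage (randomization, dropout,
compliance, calendar, training, assessments) from one master seed, so
stages can be re-run independently and `(config, seed)` determines every
output byte. `write_dataset()`/`read_dataset()` round-trip the dataset
through UTF-8 CSV plus a JSON manifest carrying the master seed, the
derived component seeds, the package version and a configuration hash.
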