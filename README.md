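# adaptrain

Adaptive signal-to-noise cognitive training trials, in silico.

Children with ADHD struggle both to resolve goal-relevant sensory signals
and to suppress goal-irrelevant distraction. A neuroplasticity-based
training approach addresses both at once: exercises that adaptively make
the attended target more subtle, and exercises that adaptively make
distractors more target-like, each held at a challenging-but-tractable
difficulty by a staircase controller. Evaluating such a program properly
means a double-blind randomized controlled trial — blocked 2:1 allocation
stratified by medication status, a 30-hour dose over six months, parent
symptom ratings at four timepoints, a cognitive battery at baseline and
post — and a specific nonparametric analysis plan for the small samples
such trials recruit.

`adaptrain` implements that entire design as a simulation laboratory for
methodologists and trialists: the 25-exercise adaptive curriculum, virtual
subjects with psychometric observers and latent traits, the assessment
battery, the trial engine, and the statistical pipeline — so the design can
be exercised, power-checked and validated end-to-end without clinical data.
Real assessment tables in the same long schema can be ingested and analyzed
with the identical pipeline.

## The models at the core

**Staircase.** Difficulty lives on a challenge axis c ∈ [0, 1]. The
3-down-1-up transformed up-down rule raises c by a step after three
consecutive correct responses, lowers it after any error, and halves the
step at each reversal (floor 0.01). It converges where p³ = ½, i.e. at
p ≈ 0.794 correct — inside the designed 75–85% performance band.

**Observer.** A subject with trait t answers a trial at challenge c
correctly with probability

    P(correct) = γ + (1 − γ − λ) · F((t − c)/σ),

the lapse-corrected logistic psychometric function (γ = 0.5 for 2AFC).
Training moves traits by a saturating rule, Δt = r·m·(1 − t) per m trained
minutes, with per-subject log-normal responsiveness.

**Outcome coupling.** The parent-rated symptom total (0–54) is
`intercept − β·(distractor suppression) + noise`, so only trained
distractor suppression moves the clinical outcome; β = 0 gives a null
generator for calibration.

**Analysis.** Wald–Wolfowitz runs tests, Friedman and Kruskal–Wallis rank
ANOVAs, Wilcoxon matched-pairs tests (exact small-sample nulls, computed
from the defining formulas and verified against brute-force enumeration),
Levene checks, a split-plot mixed ANOVA on five cognitive change scores,
Hedges–Olkin bias-corrected effect sizes, d′ = z(hit) − z(FA) with the
log-linear correction, and the Pearson correlation of distractor-error
change against symptom change.

## Worked example

```r
library(adaptrain)

# 1. validate the adaptive controller against a simulated observer
sim <- simulate_staircase(logistic_observer(), n_trials = 2000, seed = 1)
glance(sim)[, c("accuracy", "converged_challenge", "n_reversals")]
#> # A tibble: 1 × 3
#>   accuracy converged_challenge n_reversals
#>      <dbl>               <dbl>       <int>
#> 1    0.794               0.434         436

# 2. simulate a full trial on a 31-child virtual cohort
cohort  <- generate_cohort(cohort_config(), seed = 1)
dataset <- run_trial(cohort, seed = 1)
dataset
#> <trial_dataset> 31 subjects, seed 1, granularity 'session'
#>            completer dropout partial
#>   control          9       1       0
#>   training         9       1      11
#>   training sessions: 1233; assessment rows: 576

# 3. run the complete analysis plan
analysis <- analyze_trial(dataset)
glance(analysis)
#> # A tibble: 1 × 11
#>   n_completers n_controls n_partials arm_F  arm_p interaction_F interaction_p
#> 1            9          9         11  6.72 0.0196          2.73        0.0368
#>   hedges_g_post hedges_g_followup fig5_r fig5_p
#>           2.03              2.20  0.532  0.140
```

Reading the output: the staircase held the simulated subject at 79.4%
correct and converged on challenge 0.434, the level where this observer's
psychometric function crosses the 3-down-1-up equilibrium. The simulated
trial randomized 21:10, lost one subject per arm after baseline, and about
half the training arm trained only partially — the compliance structure the
generator is built around. The mixed ANOVA on the five cognitive change
scores gives its between-arm effect with df (1, 16) and the
arm × assessment interaction with df (4, 64); `hedges_g_post` is the
bias-corrected standardized group difference in symptom-rating change, and
`fig5_r` is the correlation, among training completers, between the change
in embedded-probe distractor false positives and the change in symptom
ratings. `tidy(analysis)` returns every test as one row;
`autoplot(dataset)` and `autoplot(analysis)` draw the rating trajectories
and the correlation scatter.

A thin CLI wraps the same functions
(`inst/cli/adaptrain.R simulate-cohort | run-trial | analyze |
staircase-validate`), with YAML/JSON configuration via `load_config()`.

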