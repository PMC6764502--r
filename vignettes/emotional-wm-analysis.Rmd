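---
title: "Scoring and analyzing continuous-report emotional working-memory tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analyzing continuous-report emotional working-memory tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emowm)
```

## The measurement problem

Delayed-estimation ("precision") working-memory tasks ask participants to
reproduce a remembered feature on a continuous dial rather than to recognize
it. When the feature is the emotional expression of a face — morphed from
fearful through neutral to happy — the response lives on a bipolar valence
scale. `emowm` encodes that scale as signed integers: fearful intensities are
−100..−1, neutral is 0, happy intensities are +1..+100. This single encoding
separates two things that accuracy-based designs conflate:

* **precision** — how far reports land from targets, regardless of direction;
* **emotional bias** — whether reports are systematically shifted toward the
  happy (positive) or fearful (negative) end.

The package scores trial tables from such tasks, generates the balanced trial
schedules the design calls for, simulates complete cohorts from an explicit
generative model so that the entire pipeline can be exercised and validated
without any participant data, and runs the group-level inference.

## The design

The working-memory (WM) task is 8 blocks × 20 trials. Targets are drawn from
two morph continua (fearful, happy) at 20 intensity levels — 0% to 45% and
55% to 100% in 5% steps, omitting 50% so every emotional face has a majority
emotion. Each (emotion condition, intensity) cell appears exactly 4 times
(80 trials per condition); each of 10 facial identities appears exactly
16 times and under both conditions; conditions are intermixed within every
block. The perceptual matching task repeats the design at 2 blocks × 20
trials with each cell appearing once, and with the identity-intensity pairing
constrained to differ from the WM task. `build_wm_schedule()` and
`build_matching_schedule()` produce these schedules by seeded rejection
sampling over identity permutations; every count invariant is asserted by
brute-force tallying in the test suite.

One representational subtlety: the 0%-intensity trials of both continua are
physically the same neutral face. Schedules therefore carry an
`emotion_condition` label (which continuum scheduled the trial — this is the
level at which "80 trials per emotion type" holds), while trial tables label
those trials `target_emotion = "neutral"` with `signed_target = 0`.

## Scoring

With targets and responses both signed, the per-trial measures are:

* **error** `|target − response|`: a 20% fearful target (−20) reported as
  15% fearful (−15) scores 5; reported as 15% happy (+15) it scores 35.
  The maximum over the scale is 200, and for a target of magnitude *m* it is
  *m* + 100 — both verified by exhaustive enumeration.
* **bias** `response − target`: positive means reported happier / less
  fearful. Bounded by ±200.

Participant-level summaries (`score_trials()` and friends):

* **mean error**: mean absolute error over retained trials.
* **overall bias**: the mean of the psychometric curve — the mean signed
  response per signed-intensity condition, averaged over the 39 conditions
  (including neutral). A perfectly unbiased responder scores 0 by the
  symmetry of the design. The curve-mean phrasing makes each condition count
  equally; `weights = "trial"` switches to the raw trial mean, which differs
  only once exclusions unbalance the design. Condition cells emptied by
  exclusions are dropped, not imputed.
* **per-emotion bias**: responses on fearful trials are sign-flipped so both
  emotions share a positive scale, neutral targets are excluded, the 19
  nonzero condition means are averaged, and 50 is subtracted. The
  conventional subtract-50 normalizer is kept as the default even though the
  design grid's true mean is 1000/19 ≈ 52.63, so an exactly unbiased
  responder scores +2.63 rather than 0; `normalizer = "exact"` subtracts
  1000/19 instead. Group *differences* are unaffected by the choice.
* **block feedback**: 100 − block mean error, the score shown to
  participants after each block.
* **binned psychometric curve**: for display, responses are binned by signed
  target into five 20%-wide fearful bins (the −20 bin covering −20..−1), a
  neutral bin, and five mirrored happy bins.

Exclusion variants (`apply_exclusions()`) reproduce the analysis filters:
dropping wrong-emotion-type reports, additionally dropping neutral targets,
or dropping trials that consumed the full 11-s response window. A response of
exactly 0 on an emotional target reports *no* emotion type: it is not a
wrong-emotion trial and is retained by the wrong-emotion filter, but it is
excluded (from numerator and denominator) in the valence analysis, where only
categorizable reports are informative. Both choices are asserted in tests.

## Valence categorization

`categorize_trial()` classes each emotional-target trial by the sign match of
target and response. Proportion correct is computed per target emotion in
five absolute-intensity bins (1–20, …, 81–100), and `proportion_slope()`
summarizes each participant's curve by its ordinary least-squares slope
against the bin index 1..5 (units: proportion per bin step). Bin index rather
than bin-center intensity is the regressor: per-step slopes are the scale on
which such curves are conventionally reported, and with five equally spaced
bins the two choices differ only by a factor of 20. One-sample t tests on
slopes and on happy-minus-fear slope differences test the intensity
dependence of miscategorization.

## The generative simulator

`simulate_responses()` implements a deliberately simple response model — it
exists to exercise the pipeline and support parameter recovery, not as a
claim about mechanism. On each emotional trial, with probability

p_flip(i) = `flip_base_rate` · exp(−i / `flip_decay`)

(at absolute intensity i) the valence is miscategorized: the response takes
the opposite sign with magnitude |N(15, 10)| clipped to 1..100, mimicking the
concentration of misinterpretation at ambiguous low intensities. Otherwise
the response is the target plus a signed per-emotion `bias_shift` plus
N(0, `noise_sd`), rounded to the 1% morph steps of the dial and clipped to
the scale. Neutral targets get pure noise around 0. Trials time out with a
fixed probability, in which case the response stands and the response time is
pinned at the 11-s maximum.

Default parameters (`default_cohort_params()`) encode the qualitative
structure the task was built to detect, fixed once as the package's study
conditions: report noise around 11–14% (yielding mean errors in the upper
teens), a +4% fearful-target shift in the older group (fearful faces
remembered as less fearful), and flip base rates of 0.2–0.5 tuned so that
whole-task wrong-emotion proportions land near the 5–15% range typical of
this paradigm. Each participant draws from an independent RNG substream, so
cohort composition never perturbs another participant's data.

What the simulator does *not* emulate: set-size effects, response-time
structure beyond a lognormal placeholder, identity- or stimulus-specific
difficulty, serial/block effects, and any real covariance between anxiety
and behavior. Passing tests on simulated data therefore validate the
*arithmetic and inference machinery*, not psychological conclusions.

Two identifiability notes, verified in the tests:

* a pure fearful-target shift of +4 propagates to an old-minus-young overall
  WM bias difference of exactly 19·4/39 ≈ 1.95, since 19 of the 39 intensity
  conditions are shifted; parameter recovery at n = 50 per group and noise
  SD 12 recovers this within Monte-Carlo error;
* naive wrong-emotion counting recovers the flip curve only when report
  noise is small relative to the lowest intensity (the recovery test uses
  SD 1): with SD ≈ 12, noise itself carries low-intensity responses across
  zero, inflating apparent flips. Estimating flip rates under high noise
  would require a mixture model, which is out of scope.

## Group-level inference

`welch_t()` (unequal-variance, Satterthwaite df), `paired_t()`, and
`one_sample_t()` report Cohen's d with confidence intervals obtained by
inverting the noncentral t distribution in its noncentrality parameter
(`cohens_d_ci()`). Between-group d uses the pooled SD; the paired effect size
is d_z (mean difference / SD of differences), with the pooled-SD variant also
reported since conventions differ. Note that exactly identical paired vectors
have zero-variance differences and no defined t; the package raises an error
rather than returning 0/0.

`mixed_ancova()` fits the mixed repeated-measures AN(C)OVA via a
multivariate linear model on the wide data with Type III sums of squares and
effects-coded factors — the convention of the established repeated-measures
packages. Between-subject factors are fully crossed with each other and with
the within-subject factors; covariates (continuous ones centered, so main
effects are evaluated at the covariate mean) enter the between model
additively, as "covariates of no interest" conventionally do. Sphericity of
within effects with ≥3 levels is assessed by Mauchly's test at α = .05, and
Greenhouse–Geisser-corrected degrees of freedom and p values are reported
when it rejects (`gg = "auto"`; `"always"`/`"never"` override). Mauchly's
test is the explicit, standard trigger for the correction; two-level within
factors need none (ε is undefined at k = 2). Partial η² is
SS_effect/(SS_effect + SS_error) with a 90% CI from the noncentral F
(`eta_sq_ci()`); 90% is the conventional level because the F test is
one-sided in λ. Degenerate inputs are explicit errors: incomplete
within-cells, collinear covariates; constant covariates are dropped with a
message so an ANCOVA degrades gracefully to the ANOVA.

Calibration is tested, not assumed: under a pure null, the empirical type-I
rate of each effect across 1,000 simulated cohorts is checked against .05
within binomial error, and the 90% η² CI attains ≈ 90% coverage under a known
noncentrality.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → score → valence → analyze, writing tidy
CSVs plus a JSON manifest (seed, configuration hash, package version,
exclusion counts). Every artifact is a pure function of the configuration;
rerunning a config reproduces the outputs byte-for-byte, which the test suite
asserts. Configurations can be read from YAML (`read_pipeline_config()`),
and `inst/cli.R` exposes the stages as shell subcommands.

Problem sizes used in the shipped tests — cohorts of 2–6 per group for
plumbing checks, 50 per group for parameter recovery, 1,000 replicates for
calibration — were chosen as the smallest sizes at which the Monte-Carlo
bands in the corresponding checks are meaningfully tight.

## Known limitations

* The simulator's flip-magnitude distribution (folded normal at 15 ± 10) is
  a convention; only its qualitative property (low-to-moderate opposite-sign
  reports) matters for the analyses.
* The exact pseudo-randomization constraints tying identities to restricted
  intensity ranges in the original stimulus set are not reproduced; the
  governing constraint is the per-identity trial count and both-condition
  coverage.
* `mixed_ancova()` requires complete within-subject data; participants with
  empty cells after aggressive exclusions must be handled upstream.
* No mixture-model decomposition of report errors (guess rate vs precision)
  and no likelihood fitting of the generative model are provided.
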