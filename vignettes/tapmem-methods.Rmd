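---
title: "Methods: from tap-event logs to digital memory biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tap-event logs to digital memory biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapmem)
```

## The measurement problem

Smartphone-administered memory tests produce streams of timestamped tap
events rather than a single score. Two confounds make naive scoring of such
streams misleading in neurological populations: sensory-motor slowing (a
subject with hand weakness taps slowly regardless of cognition) and the
all-or-nothing character of pass/fail level scoring (two subjects who both
fail a pattern may differ enormously in how close they came). `tapmem`
addresses both with a latency decomposition and a partial-credit accuracy
model, then aggregates the resulting biomarkers into composite scores with
standard ordinal regression machinery.

## Test mechanics assumed by the data model

Four stages are modelled. The verbal test presents ten word pairs, then asks
the subject to pick each cue's partner from four options; a perfect 10/10
ends the trial and any error triggers a repeat attempt. The same procedure is
repeated after a delay (immediate vs. delayed recall). The spatial test shows
checkerboard patterns of 4–8 squares on a 4×4 grid (every square adjacent to
another by at least a corner); correct reproduction advances the level,
errors repeat it with a fresh pattern, and the whole stage is capped at five
attempts. The dynamic spatial stage additionally requires the squares to be
tapped in their presentation order. Every selection and deselection is
timestamped (integer milliseconds from trial start, so logs carry no float
drift; derived intervals are reported in seconds).

## The latency decomposition

For each trial the minimal inter-tap interval

$$\mathrm{iSMPT} = \min(\Delta t_1, \ldots, \Delta t_n)$$

is taken as an individualized sensory-motor processing threshold: the fastest
tap a subject produces carries the least cognitive load, so its latency
approximates pure sensory-motor delay (plus an irreducible minimum of
processing). Subtracting it from the trial's mean interval gives the
adjusted recall latency

$$\mathrm{RLa} = \overline{\Delta t} - \mathrm{iSMPT},$$

which is non-negative by construction and isolates the latency attributable
to cognitive demand. The decomposition has a sharp algebraic signature that
the test suite exercises: adding a constant to every interval (pure motor
slowing) shifts iSMPT by that constant and leaves RLa unchanged.

Two aggregation choices were open. First, all tap events — selections *and*
deselections — enter the interval stream, because the raw logs timestamp
every tap and the decomposition is defined over consecutive taps of any
kind. Second, the interval preceding the first tap of an attempt (from
stimulus onset) is *not* part of the stream: stimulus-onset times are not
part of the log schema, and including them would mix display latency into a
motor statistic. Both choices are enforced by `inter_tap_intervals()`.

`RLa` uses the mean interval rather than the sum so that trials of different
lengths (different attempt counts) remain comparable; the mean of
per-interval excesses over the floor is identical, which the tests verify.

## Accuracy: partial credit and the log-impairment scale

Passed spatial levels earn their full square count (maximum
4+5+6+7+8 = 30). For the highest failed level, credit is the level's square
count minus the mean number of incorrect taps across all attempts at that
level, floored at zero. The dynamic stage double-weights both the level
counts (maximum 60) and the mistake penalty, reflecting the doubled demand
of serial-order reproduction. A worked example: passing 4 and 5 and then
failing level 6 with 3 and 1 mistakes across two attempts yields
4 + 5 + (6 − 2) = 13; a failed dynamic level 6 with a mean of 2 mistakes
yields 12 − (2 × 2) = 8.

Raw accuracy scores are inverted against their maximum and
log10-transformed so that higher values mean greater impairment:
`SRI = log10(max − raw + 1)`, `VRI = log10(100 − pct + 1)`. The `+1` shift
is a deliberate numerical choice: the bare transform is undefined at perfect
scores, while the shifted one anchors flawless performance at exactly 0.
Because the shift is monotone, every rank-based downstream statistic
(Wilcoxon tests, Spearman correlations, the ordinal fits) is unaffected.

Two distinct mistake counts are maintained on purpose. Partial credit uses
*all* incorrect taps of an attempt; the self-correction biomarker SRM counts
only errors that were tapped and then deselected
(`SRM = log10(count + 1)`). The first measures reconstruction accuracy, the
second error monitoring.

Verbal accuracy uses the *first* attempt only: repeat attempts exist only
after errors, so pooling them would systematically dilute the accuracy
signal of impaired subjects. The delayed stage uses the identical transform.

This yields the 14-biomarker vector per subject-session: four iSMPT values
(verbal immediate/delayed, spatial static/dynamic), four adjusted latencies,
four impairment scores, and two spatial mistake counts.

## Integrity checks

Exclusion is at trial level only; nothing is imputed. The configurable
defaults treat an inter-tap interval under 150 ms as anticipation, one over
300 s as abandonment, and a trial longer than 30 minutes as invalid. The
criteria are part of the pipeline's contract; the specific thresholds are
plausible bounds for a supervised-or-home smartphone setting and are
exposed in `integrity_rules()` rather than hard-coded.

## Composite modelling

Diagnostic groups are placed on an ordered impairment continuum
HD < RR-MS < P-MS (progressive MS pooling its secondary and primary forms);
other diagnoses are scored but never fit. A cumulative-logit
proportional-odds model (`MASS::polr`) returns one weight per biomarker and
two ordered thresholds; the *linear predictor* on z-standardized features
serves as the composite score. Standardization makes coefficients comparable
across biomarkers with different units; the linear predictor (rather than a
predicted class probability) was chosen because it is threshold-free,
continuous, and preserves the fitted ordering — the natural candidate for a
"composite score" when the scoring formula itself is not prescribed. Its
orientation is fixed empirically (mean P-MS score above mean HD score on the
training data) so that higher always means more impaired. Ten-fold
cross-validated classification accuracy is reported alongside the fit; a
single fixed proportional-odds fit replaces any learner search, since the
proportional-odds model is the final published form of such composites.

The cohort protocol is: MS subjects are split 2/3 train vs. 1/3 validation,
stratified on SDMT quartiles (ties broken by `ceiling`, so 217 subjects
split 145/72); training uses up to the first 10 consecutive sessions per
subject, validation exactly the first; healthy donors anchor the model in
both roles. Wald odds ratios with 95% CIs accompany each fit, and group
contrasts use Wilcoxon rank-sum (or signed-rank for paired data) with raw
p-values — no multiplicity adjustment, matching the reporting convention
the pipeline implements.

## SDMT quality control

Because the spatial test and the Symbol Digit Modalities Test tap
overlapping constructs (processing speed plus visuospatial working memory),
observed SDMT scores should be predictable from the eight spatial
biomarkers. `fit_sdmt_model()` fits that regression,
`stepwise_reduce()` applies bidirectional AIC search (`MASS::stepAIC`
defaults), and `predict_with_interval()` builds the exact t-quantile
prediction interval for a *new* observation — residual variance plus the
leverage term — rather than the ±1.96·RMSE shortcut, which undercovers
away from the training centroid and at small n. An observed SDMT outside
its envelope is flagged discordant: a data-driven, unsupervised
quality-control signal. The envelope is constructed around the original
multivariate fit (not around an observed-on-predicted re-regression), which
is the interpretation consistent with conditioning on spatial performance.

Agreement between observed and predicted scores is quantified by Spearman's
rho, R², and Lin's concordance correlation coefficient with population
(n-denominator) moments, Lin's original convention. Confidence intervals
for such statistics use a nonparametric bootstrap resampling *participants*
(all rows of a drawn subject travel together, B = 2000, percentile method —
the minimal faithful reading of a participant-level bootstrap).

## Reliability battery

Test–retest reliability is the between-subject share of variance from a
REML random-intercept model (`lme4`):
`ICC = σ²_b / (σ²_b + σ²_w)`, with a 95% CI from a parametric bootstrap of
the fitted model (500 replicates by default). Exact repeats are detected
before fitting and reported as ICC 1; zero between-subject variance yields
ICC 0 with a degenerate-CI note. Conventional bands label 0.50–0.75
moderate, 0.75–0.90 good, ≥0.90 excellent.

Averaging four consecutive trials uses non-overlapping blocks (remainder
dropped), not running means: block means of iid noise are then independent
and the expected within-subject variance reduction is exactly 1 − 1/n
(75% at n = 4). A real longitudinal trend is preserved by averaging and
bounds the observed reduction below that — which is why observed reductions
on real series exceed or undershoot 75% depending on their temporal
structure.

Age norms regress score on age in a healthy reference cohort collapsed to
per-subject yearly medians (median score and age per calendar year), with a
90% new-observation prediction band. Query trials are flagged only when
*above* the band: all scores are oriented so higher is worse, and the
clinically relevant deviation is impairment, not supranormal performance.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without any participant data. It emulates exactly the features the analysis
relies on:

* **Inter-tap intervals** are `motor_floor + cog_latency_scale × demand +
  Exp(motor_jitter)` — a shifted exponential. Any noise with positive
  density at zero after the shift makes `min(Δt)` converge to the shift, so
  the iSMPT estimator's intent is exactly testable; the exponential is the
  simplest such choice. Demand is 1 for verbal/static and 2 for the dynamic
  stage.
* **Pass/fail per level** is Bernoulli with probability
  `plogis(1.4 × (memory_capacity − level))`, dynamic stages half a level
  harder; mistake counts on failed attempts are truncated-Poisson with rate
  growing in (level − capacity); a configurable fraction of errors is
  self-corrected (select, deselect, replace).
* **Patterns** grow by corner-adjacent accretion (each new cell within
  Chebyshev distance 1 of the current pattern) — one valid reading of the
  adjacency rule; the production app's algorithm is not public.
* **Group structure**: healthy donors, relapsing-remitting and progressive
  MS at motor floors 0.24/0.30/0.40 s, cognitive latencies
  0.35/0.55/0.80 s per unit demand, capacities 7.0/6.2/5.2 and lapse rates
  2/5/10% — an ordered impairment gradient with realistic overlap between
  adjacent groups.
* **SDMT** is linked to the same latents:
  `90 − 40·cog_latency_scale − 45·motor_floor + N(0, 7)`, truncated to
  [0, 110], putting group means near 65/55/40 — so spatial biomarkers carry
  genuine but imperfect SDMT signal, as a cross-validating test should.
* **Sessions** repeat weekly with independent Gaussian jitter
  (SD 0.03 s) on the cognitive latency; enough temporal structure for ICC
  and averaging analyses without claiming any particular longitudinal
  dynamics.

Everything is deterministic given `(config, seed)`; written logs round-trip
byte-stably through the canonical JSON writer. What the generator does
*not* emulate: real demographic distributions, practice effects, device
heterogeneity, word-list semantics, or the empirical shapes of real
interval distributions beyond their floor-plus-noise structure.
Consequently, passing tests demonstrate that the pipeline's estimators
recover what they claim to estimate under the stated generative
assumptions — not that real cohorts will reproduce any particular effect
size.

## Problem sizes and numerical choices in the test suite

The suite exercises parameter recovery at sizes chosen to make sampling
noise negligible relative to the tolerance being asserted: 1,000 sessions
for the iSMPT floor recovery (median within 15%), n = 2,000 for
proportional-odds coefficient recovery (within 2 SE), 200 train/validation
draws of n = 500 for prediction-interval calibration (coverage in
[93%, 97%]), 50 seeds of 100 subjects × 4 visits for ICC recovery (median
within ±0.05 of the true 0.75), and 1,000 series for the 1 − 1/n averaging
property. Ties in the quadrant median split go to the "low" side; stepwise
selection keeps `stepAIC`'s default AIC penalty, under which occasional
admission of a null predictor is expected behaviour, and the tests assert
retention of true predictors rather than exact support recovery.

## A worked pipeline run

```{r pipeline, eval = FALSE}
cohort <- simulate_cohort(sim_config(groups = default_group_specs(25L),
                                     seed = 11, sessions_per_subject = 2))
b <- cohort$biomarkers

# composite over the six cognition-specific spatial biomarkers
feats <- c("StaticSRLa", "DynamicSRLa", "StaticSRI", "DynamicSRI",
           "StaticSRM", "DynamicSRM")
model <- fit_ordinal_composite(b, feats, seed = 2)
b$score <- composite_score(model, b)
compare_groups(b$score, b$group)

# SDMT envelope QC
sdmt_fit <- stepwise_reduce(fit_sdmt_model(b))
qc <- predict_with_interval(sdmt_fit, b, observed = b$sdmt)
table(qc$flag)

# reliability of the composite across repeated sessions
icc_random_intercept(b, score = "score", nboot = 200, seed = 3)
```

## Known limitations

* The proportional-odds composite assumes proportional odds; no formal test
  of that assumption is run, matching the pipeline it implements.
* iSMPT is a minimum statistic: it is upward-biased at small tap counts
  (the bias of the minimum of n shifted-exponentials is 1/(n·rate)) and has
  no robustness to a single spuriously fast tap below the anticipation
  floor — which is why the integrity floor matters.
* The ICC bootstrap CI is parametric and inherits the normality assumptions
  of the mixed model.
* The age-norm band assumes a linear age effect in the reference range;
  extrapolation beyond it is flagged but not prevented.
* Synthetic validation cannot establish clinical validity; it establishes
  computational correctness and statistical calibration of each estimator.
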