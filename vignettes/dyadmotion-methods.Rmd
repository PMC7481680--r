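---
title: "Methods behind dyadmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dyadmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmotion)
```

This vignette documents the statistical and numerical choices in
`dyadmotion`: how raw skeleton streams become condition-level measures of
proxemics, gaze and interpersonal synchrony, and how each stage is
validated against ground truth from the synthetic generator.

## Data model

A session holds, per participant and per sensor, a `skeleton_stream`:
irregular timestamps, five joints (head, neck, both shoulders, a spine
reference) as N×3 matrices, head orientation as yaw/pitch/roll, and a
per-sample validity mask. Coordinates are right-handed with y up, in
metres; yaw 0° looks along +z, positive yaw turns toward +x, so
`gaze_vector(yaw, pitch)` is
$(\cos p \sin y,\; \sin p,\; \cos p \cos y)$.
Trial annotations give condition windows; subject scores hold the
questionnaire ratings. Everything round-trips through a plain-CSV on-disk
layout (`write_session()` / `read_session()`) that is invariant to row
order and validates mandatory columns.

## Preprocessing

`resample_uniform()` linearly interpolates every channel onto a uniform
10 Hz grid. A sample on the new grid is valid only when its bracketing
raw samples are valid and no bridged gap exceeds 1 s; yaw is
interpolated on the circle to respect the ±180° seam.

`gaussian_lowpass()` smooths with a truncated Gaussian kernel
(σ = 0.5 s, support ±4σ) that is *mask-aware*: at each output sample the
kernel weights are renormalized over the valid inputs only, so missing
stretches neither bleed zeros into the estimate nor shrink it toward the
gap. `compute_speed()` uses central differences; a speed sample is
masked when the sample itself or any contributing neighbour is masked.

Aggregation is two-stage everywhere: values are averaged within a trial
first and across same-condition trials second, so long trials do not
dominate a condition mean.

```{r preprocess-demo}
n <- 200
fixed <- function(x, y, z) cbind(rep(x, n), rep(y, n), rep(z, n))
st <- skeleton_stream(
  participant_id = "p1", sensor_id = "k1",
  timestamps = sort(runif(n, 0, 20)),
  joints = list(head = cbind(sin(seq_len(n) / 20), 1.2, 0),
                neck = fixed(0, 1, 0), shoulder_left = fixed(-0.2, 1, 0),
                shoulder_right = fixed(0.2, 1, 0),
                spine_shoulder = fixed(0, 1.05, 0)),
  head_orientation = fixed(0, 0, 0))
u <- gaussian_lowpass(resample_uniform(st))
c(rate = u$rate, n = length(u$t), valid = mean(u$valid))
```

## Registration

Sensors disagree in space and time. `fit_rigid_transform()` solves the
orthogonal Procrustes problem with the SVD (Kabsch) construction,
flipping the smallest singular direction when needed so that
$\det(R) = +1$ always — noiseless planted transforms are recovered to
<1e-9. `register_sensors()` applies it to the co-visible registration
landmarks; `temporal_realign()` estimates residual clock offset by
cross-correlating the two sensors' speed series and warns when the peak
correlation is weak. Identity swaps after occlusions are repaired by an
SVM on per-frame joint positions (`train_identity_model()`), which the
seating geometry makes essentially separable.

## Proxemics

`relative_yaw()` is the unsigned angle in [0°, 180°] between the
projection of the facing direction onto the horizontal plane and the
horizontal direction to the partner's head; `body_direction()` supplies
the facing vector for the body channel as the shoulder-line normal
oriented away from the spine reference. The two participants'
simultaneous relational yaws feed a 2-D histogram in 1° bins normalized
to sum to exactly 100 (percent of valid time). Smoothing uses a 5°
Gaussian with edge renormalization, so the sum stays 100 after
smoothing. Condition effects are assessed per cell with a
repeated-measures ANOVA (dyad as the repeated unit); pairwise paired
t-maps are *gated* by the ANOVA mask so that pairwise differences are
only reported where a condition main effect exists.

```{r proxemics-demo}
h <- joint_orientation_histogram(runif(500, 0, 90), runif(500, 0, 90))
c(raw = sum(h), smoothed = sum(smooth_histogram(h, sigma = 5)))
```

## Gaze

Human raters answer two binary questions per sampled frame and
participant: looking at the partner? looking at the shared target?
`merge_annotations()` takes two primary raters per question and lets a
third rater break ties; `dyadic_gaze_label()` maps the merged answers of
both participants to four dyadic categories with partner-precedence
(mutual partner-looking is `eye_contact` regardless of target answers).
With per-rater error rate $e$, two-rater percent agreement is
$1 - 2e(1-e)$; the annotation simulator reproduces this analytically
calibrated relation.

The classifier is a hand-written Gaussian naive Bayes on head-pose
features (both relational yaws, pitches, inter-head distance and gaze
vectors): classes are balanced by subsampling, priors are uniform,
features standardized, and per-class variances floored at 1e-6.
Evaluation uses repeated stratified half-splits and leave-one-dyad-out,
both reporting *mean per-class* accuracy so that imbalanced categories
cannot inflate the summary; a label-permutation null band calibrates
chance (~25%).

Prevalence (percent of valid time per condition) comes from counting
predicted labels. Because even a good classifier shifts prevalence
systematically, `predict_prevalence()` optionally applies adjusted
classify-and-count: with row-normalized confusion matrix $C$ (truth ×
predicted, from cross-validation), it solves
$C^\top p_{\text{true}} = p_{\text{obs}}$, clips negatives and
renormalizes. On synthetic sessions with 5° orientation noise this
brings worst-case prevalence error under 1 percentage point.

## Synchrony

For speed series $x, y$ on a uniform grid, `windowed_crosscorr()`
computes, for every 30 s window (step 1 s) and every lag $\ell$ up to
±max_lag samples, the Pearson correlation of the $m = W - |\ell|$
overlapping samples inside the window, each segment centred by its own
mean. The implementation uses cumulative-sum algebra over precentred
series and is tested to agree with a naive per-window, per-lag `cor()`
recomputation to 1e-12; the identity
$\mathrm{ccf}_{xy}(\ell) = \mathrm{ccf}_{yx}(-\ell)$ holds exactly by
construction. Positive lag means participant 1 leads. Windows containing
masked samples or near-constant segments yield `NA`.

Window matrices average into a per-condition mean function
(`mean_ccf()`, which also pools across trials or dyads when given a
list). Two peak summaries exist: `pick_peak()` returns the positive
strict local maximum with the smallest absolute lag (ties prefer
participant 1 leading, zero-lag fallback when no local maximum exists),
matching the "is there synchrony near zero lag" question;
`estimate_coupling_lag()` returns the global maximum refined by
three-point parabolic interpolation, matching the "where is the planted
coupling" question.

Chance levels come from shuffled-dyad surrogates: participant 1 of one
dyad/trial is paired with participant 2 of a *different* dyad and a
*different* trial index, destroying genuine coupling while preserving
marginal dynamics. Condition contrasts run a repeated-measures ANOVA at
every lag and report the fraction of lags with a significant condition
effect.

## Inference

`partner_agreement()` correlates the two partners' ratings per score.
`correlate_behaviour_scores()` supports one- and two-tailed tests with
Bonferroni correction. The outlier-robust check
(`partial_correlation_outlier_control()`) partials a 3-SD outlier
indicator out of both variables in closed form (verified against
`lm()`-residual correlations) instead of silently excluding dyads.
`permutation_check()` re-derives p-values by sign-flipping (paired t) or
label shuffling (correlation) with an add-one numerator so permutation
p-values are never exactly zero.

## Synthetic generator and what it taught us

`generate_dyad()` plants every quantity the pipeline estimates: seats
and therefore inter-head distance; semi-Markov gaze bouts with
per-condition occupancy and dwell; band-limited (0.1–1 Hz) head sway;
movement coupling $x_2 = \sqrt{1-a^2}\,\varepsilon + a\,x_1(t - L)$ on
the per-axis position noise; a rigid between-sensor transform, sensor
noise, a clock offset; i.i.d. frame drops. `generate_cohort()` adds
dyad-level questionnaire scores with planted behaviour–score
correlations via sample-standardized mixing.

Two generator-driven findings shaped the estimators. First, because
speed is the norm of the velocity, a position-noise mixing of $a$
yields a speed cross-correlation of roughly $a^2$ — weak coupling is
much harder to see in speed than in position. Second, band-limited sway
has an oscillatory autocorrelation, so a single dyad's cross-correlation
function carries genuine side lobes a few seconds from the true peak
that occasionally exceed it when coupling is weak; pooling windows
across many dyads before peak-picking (as group-level synchrony analyses
do) suppresses these lobes, and that is how the acceptance suite
validates lag recovery.

```{r synchrony-demo}
sched <- data.frame(condition = "cooperative", duration_s = 300)
g <- generate_dyad(dyad_config(schedule = sched, seed = 1,
                               coupling = list(lag_s = 1, strength = 0.8,
                                               channel = "head")))
u1 <- gaussian_lowpass(resample_uniform(g$session$streams$p1$k2))
u2 <- gaussian_lowpass(resample_uniform(g$session$streams$p2$k2))
m <- windowed_crosscorr(joint_speed(u1), joint_speed(u2),
                        wcc_params(window = 300, step = 10, max_lag = 30))
estimate_coupling_lag(mean_ccf(m, rate = 10))
```
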