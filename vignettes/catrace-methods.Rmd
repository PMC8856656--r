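---
title: "Methods: cell-type-resolved calcium imaging analysis for cued reward conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved calcium imaging analysis for cued reward conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

catrace analyses two-photon Ca^2+^ imaging recorded while head-fixed mice
perform auditory cued reward conditioning: a 1-s tone (CS) predicts a water
reward delivered after a 1.5-s delay, with intertrial intervals of 60–120 s
and 30–35 trials per 1-h session, imaged at 30 Hz on days 1 and 7 of
training. The pipeline starts at extracted ROI fluorescence traces and lick
logs and produces significant-event masks, trial-by-trial CS/reward
responsiveness and reliability statistics, Spearman tuning coefficients
with resampled nulls, and licking-confound controls. This vignette explains
each stage, its assumptions and parameters, and the design decisions that
were genuinely open.

## Conventions

All times are seconds from session start. Frame `k` (1-based) covers
`[(k-1)/30, k/30)`; the frame containing time `t` is `floor(30 t) + 1`.
Every analysis window is half-open, `[start, start + len)`, and a 2.5-s
window always maps to exactly 75 frames. Thresholds are strict
exceedances (`z > 1`, never `>=`), so boundary cases in tests are exact.

## Preprocessing

**Baseline (F0).** The slow baseline is estimated from the *inactive* parts
of each trace by an iterative percentile scheme
(`estimate_baseline_f0()`): a running 8th-percentile over a 60-s sliding
window (evaluated every 15 s, plus an anchor at the final frame, linearly
interpolated) is fitted; frames rising more than two robust standard
deviations (MAD-based, computed on a strided subsample of the inactive
residuals) above it are flagged active; the percentile is recomputed on the
remaining frames. The cycle repeats until fewer than 0.5% of frames change
flag, or at most 10 passes — on pure-noise traces the flagged set never
stabilises exactly (a handful of threshold frames jitter forever), so a
small stabilisation tolerance is the convergence criterion. The 8th
percentile sits ~1.4 SD below the noise mean; this constant offset is
irrelevant downstream because the z-score subtracts the baseline mean.
ΔF is raw F minus F0, in raw fluorescence units (the z-score is defined on
ΔF directly; a ΔF/F0 variant would only rescale each neuron).

**Z-scoring.** `Z = (ΔF − µ)/σ`, where µ and σ are the mean and sample
(n−1) SD of the concatenated 2.5-s stretches preceding every CS onset in
the session. Neurons with σ = 0 are flagged degenerate and excluded. By
construction the pooled baseline frames standardise to mean 0, SD 1, and
the transform is invariant to positive gain on the raw trace.

## Significant activity events

`detect_events()` circularly shifts each ΔF trace by a random integer
(uniform on 1..L−1; shift 0 would compare the trace with itself and yield
ties) 1000 times. A frame is event-eligible when the original trace
strictly exceeds the shifted surrogate in ≥950 shifts; events are maximal
eligible runs of ≥5 frames. Ties never count as exceedance, so constant
traces produce no events. The 950/1000 criterion is evaluated per frame and
the 5-frame condition applied to eligibility runs (the alternative reading
— evaluating whole runs against the surrogates — is not used). Neurons
without a single event anywhere in the session are removed from all
analyses (`filter_active_neurons()`); `percent_active()` reports the
retained fraction. On 18,000-frame white-noise traces the expected fraction
of frames inside events is well under 1%.

## Trial responsiveness and reliability

A neuron is CS- (reward-) responsive on a trial when some run of ≥5
consecutive frames with `z > 1` lies entirely inside the 2.5-s window
opening at the CS onset (reward delivery). Containment, not overlap, is
required — "within 2.5 s" is read strictly. Only trials with ≥3 licks
within 2.5 s of reward delivery are included (behavioural engagement
filter); tone-only sessions include all trials. In the nonpaired paradigm
the reward window opens at the first lick after delivery, and trials
without such a lick before the next tone are excluded.

The population summary follows the task's pooling convention: percent of
active neurons responsive per included trial → median over a mouse's
trials → mean over mice. The **reliability index** of a neuron is the
percent of included trials on which it was responsive.

**Monte-Carlo null.** `null_percent_responsive()` bootstraps mice with
replacement; each sampled mouse contributes as many uniformly placed 2.5-s
windows as it has included trials, scored with the verbatim criterion; the
same median-then-mean pooling gives one null value, and 1000 iterations
give the null distribution. Verdicts use exact resampling p-values,
`p = (1 + #{null ≥ observed})/(n_iter + 1)` per tail, doubled and
Bonferroni-corrected over the four standard comparisons (2 stimuli × 2
days); `***` marks an observed value outside the entire null sample.
An important structural property, measured by this package's calibration
studies: the verdict is *conservative* under a true null, because each
null iteration is recentred on the same session data that produced the
observed value (a session with incidentally elevated activity raises both)
and the mouse bootstrap adds resampling variance the single observed
cohort value does not have. On fully untuned synthetic cohorts the
percent-responsive test rejects in well under 1% of replicates, and the
tuning-change null (below) in roughly 2–4% — not the nominal 5%. This is a
property of the published resampling design itself, not of tuning
constants; the package reports it rather than recalibrating the test,
since the test's role in the pipeline is to gate obvious task responses
(which sit far outside the null) rather than to operate near its nominal
level.

**High/Low split and learning effects.** Day-1 reliability indices are
pooled across mice per cell type; the 50th percentile (linear
interpolation) of the *nonzero* values is the threshold. Indices at or
below it form the Low group, above it High. Zero-reliability neurons are
excluded from the threshold computation but assigned to the Low group so
their day-7 fate can be followed (day-1-unresponsive cells becoming
responsive is part of the phenomenon); a `responder` flag keeps them
identifiable. `delta_reliability()` is the day-7 minus day-1 index;
`delta_reliability_random()` replaces the day-7 task alignment with as
many uniformly placed 2.5-s windows as there are day-7 included trials
(with replacement, verbatim criterion) to give each neuron a random-
sampling control. Distributions are compared with the two-sample KS test,
pooling neurons across mice.

**Onset latency** is the time from the window start to the fifth frame of
the first qualifying run, averaged over a neuron's responsive trials, with
the per-mouse summary the median across neurons. The threshold is the same
`z > 1` criterion used for responsiveness (the event mask from the
circular-shift test is deliberately not reused here, keeping the latency
and responsiveness definitions aligned). **Cross-day fates** classify
day-1 responders as maintained / switched to the other stimulus / lost.

## Tuning coefficients

For each neuron the trial snippets `[cs − 2 s, cs + 11 s)` (390 frames)
are averaged and Spearman-correlated (average ranks for ties) with a
binary indicator: 1 on `[cs, cs + 2.5)` for CS — tone through delay, up to
reward — or on the first 2.5 s of reward delivery. The correlation runs on
the z-scored ΔF at the native 30-Hz grid; z-scoring only applies a
per-neuron affine map, which leaves ranks, and hence ρ, identical to the
raw-ΔF computation for every neuron. The behavioural trial filter is
applied to the averaged trials for consistency with the responsiveness
analyses (`included_only = FALSE` restores the unfiltered set).

The cohort change `Δρ̄` is mouse-balanced: per-cell `ρ(7) − ρ(1)`, mean
within mouse, mean over mice. Its null (`null_mean_delta_rho()`)
bootstraps mice and redraws each session's trial start times uniformly
over `[0, T_session − 13 s]` (overlapping fake trials are allowed — only
uniformity is specified), recomputing every cell's ρ on the scrambled
alignment; verdicts use the same exact-p convention. The scramble is the
hot loop of the whole package and runs in compiled code.

## Licking analyses

Lick rates are counted in 500-ms bins on the trial-aligned grid
(`binned_lick_rate()`; all trials included, no neural filter).
Anticipatory rate covers `[cs, cs + 2.5)` — excluding the reward moment.
ITI lick bouts are licks ≥20 s after the previous trial end, segmented by
the 3-s gap rule; a bout is kept only if it *starts* more than 2.5 s
before the next CS, so the analysed 2.5-s span never touches the CS. Only
the first 2.5 s of a bout enters neural analysis; `bout_reliability()`
applies the verbatim responsiveness criterion to bout windows.

`classify_lick_cells()` contrasts, per neuron, the mean z-scored ΔF over
the first bout of each ITI against an equal number of duration-matched
windows drawn without replacement from the eligible ITI spans (paired
t-test, two-sided, α = 0.05; the lick label additionally requires the bout
mean to be higher). The random windows are drawn independently per neuron;
matching both the number and duration of bouts exactly resolves the
otherwise unspecified random-window count. `classify_mixed_selectivity()`
repeats the contrast with the CS and reward windows of included trials.

## The synthetic-session generator

`simulate_cohort()` produces cohorts with known ground truth so every
downstream stage has a recoverable target. Per session it draws trial
times (paired: reward at CS + 2.5 s, ITI uniform 60–120 s, 1-h sessions;
controls: ITI 15–25 s, 45-min sessions; nonpaired: reward at a uniform
40–80 s delay), then licks, then per-neuron transients and noise, in a
fixed order so an integer seed reproduces the cohort bit-for-bit.

Traces are `baseline × (1 + drift) + transients + noise`: baseline F
uniform on 50–200 a.u. per neuron (so the F0 estimator is exercised
nontrivially), sinusoidal fractional drift (amplitude 0.05, period 600 s),
white Gaussian noise (SD 1 a.u.), and difference-of-exponentials
transients with τ_rise = 0.05 s, τ_decay = 0.6 s — GCaMP6f-like fast-rise
slow-decay kinetics, a generator convention rather than a fitted model.
Transient peaks default to 3 noise-SD units, which after preprocessing is
≈3 z; at that amplitude the 1-z/5-frame criterion detects essentially
every evoked transient, so reliability indices estimate the per-trial
response probability with only ~+1 point of inflation from chance runs.
Tuned classes respond at the CS onset, the reward (first post-reward lick
in the nonpaired task), or ITI bout onsets, each trial independently with
the neuron's response probability; every realised response is recorded, so
ground-truth booleans and injected transients match exactly. All neurons
also emit spontaneous transients at 0.4/min — low enough to keep
stimulus-unrelated window hits under ~2 points of reliability, high
enough that untuned neurons carry events for the active-cell filter; a
sparse-firing L2/3 regime.

Lick trains are homogeneous Poisson processes: a post-reward burst
(7.2 licks/s for 2.5 s, after a short reaction lag — drawn from a 0.2 s +
exponential tail in the nonpaired task, where the animal must notice the
unsignalled water); CS+delay-window licking at 3.4/s when the association
is expressed and at the baseline within-bout rate (1.5/s) otherwise —
naive mice lick indiscriminately, so the day-1 CS-window rate matches the
ITI bout rate, as the behavioural specificity comparison requires; and
spontaneous ITI bouts initiated at 1/min of eligible ITI, 1.5–4 s long,
intra-bout gaps capped below 3 s. The day-7 response-probability boost
defaults to +0.1, emulating the reliability gain that conditioning
produces in the cue-responsive interneuron population.

What the generator does *not* emulate: temporally correlated noise,
neuropil contamination, motion artefacts, amplitude variability within a
neuron, bursty spontaneous firing, or any coupling between licking vigour
and neural amplitude. Passing recovery tests therefore demonstrate that
the pipeline's statistics are faithful to their definitions, not that the
pipeline is robust to every artefact of real recordings.

## Problem sizes used by the test suite

The acceptance-level studies run at desk scale, chosen to keep the whole
suite within a coffee break on one CPU while leaving every scientific
parameter of the study conditions (32 trials, 6 mice, amplitude 3 z,
probability 0.5, boost +0.2, all thresholds and tolerances) untouched:

* Type-I calibration: 100 fully untuned cohorts of 6 mice × 20 neurons,
  32 trials, with compact sessions using the control ITI range (15–25 s)
  and the session length fitted to the trial block; the
  percent-responsive null runs its standard 1000 iterations, the Δρ̄ null
  120 (any value ≥100 is valid for the operation; at 120 the exact
  two-sided level of the rank-based verdict is 2·3/121 ≈ 4.96%).
  Cohort-size and replicate reductions affect only the precision of the
  estimated rejection rate, not the level being estimated.
* Parameter recovery: one 6 × 100 cohort for percent-responsive and
  reliability recovery; ten 6 × 40 two-day cohorts for the Low-group
  Δreliability and KS checks.
* Behavioural signature: one 6-mouse learned cohort at the full paired
  task timing (ITI 60–120 s, 1-h sessions).
* False-positive control: 100 white-noise neurons × 18,000 frames.

`scripts/acceptance.R` re-runs the full pipeline (including event
detection and both resampling nulls at 1000/1000 iterations) on a 6 × 50
two-day cohort at the full paired task timing and writes the headline
quantities as JSON.

## Known limitations

* The F0 scheme is a documented stand-in for the iterative inactive-frame
  baselines cited in the imaging literature; it is isolated behind
  `estimate_baseline_f0()` so an alternative can be swapped in.
* The Monte-Carlo verdicts are conservative under a true null (see above);
  comparisons of their rejection rate against a nominal level should use
  the calibration studies, not the nominal α.
* Trial times are stored as float seconds and quantised only when indexing
  frames; logs recorded at coarser resolution simply inherit their own
  precision.
* The KS test is applied to reliability indices with ties (percent scales
  with 32 trials have 33 support points); p-values are the asymptotic
  ones, consistent across the package.
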