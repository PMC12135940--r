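---
title: "Methods: value-modulated somatosensory processing in Go/No-Go whisker tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: value-modulated somatosensory processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Head-fixed mice run on a treadmill and touch one of two adjacent
single-whisker stimuli with their whiskers. In the **discrimination**
(Go/No-Go) task one whisker is rewarded — licking during its 1.5 s
presentation yields water (Hit), withholding is a Miss — while licking to the
other whisker is punished (False Alarm) and withholding is a Correct
Rejection (CR). In the **detection** (Go/Go) variant both stimuli are
rewarded. Single units are recorded either in primary somatosensory (barrel)
cortex (S1) or in the intermediate/deep layers of the superior colliculus
(SC), and the question is how stimulus *value* reshapes each area's map of
whisker space: preference fractions, the time course of selectivity, the role
of spike suppression, and how task readiness (Miss trials, or trials where
the water port is physically moved Away) modulates evoked and spontaneous
rates.

whiskerbias implements that analysis pipeline end to end and ships a
synthetic-session generator that emulates the statistical structure the
analyses assume, so every stage is exercised and validated on data with known
ground truth.

## The stimulus-bias statistic

Selectivity is quantified per unit and per 10 ms time bin as a neurometric
d-prime,

$$\mathrm{bias} = \frac{\mu_A - \mu_B}{\sqrt{(\sigma_A^2 + \sigma_B^2)/2}},$$

where $\mu$ and $\sigma^2$ are the mean and across-trial variance of the
spike rate in the bin for the two conditions (Hit vs CR trials, or the two
whiskers in the detection task). Positive values indicate preference for
condition A. The calculation runs every 10 ms through the response window,
giving a time-resolved selectivity series; the mean over the 300 ms
post-touch window defines a unit's preference label.

Degenerate bins — both variances zero — return 0 when the means agree and a
flagged, capped value of $\pm 10$ when they do not. The cap keeps population
heat maps finite while marking bins whose value carries no reliable scale.

**Bias relative to baseline.** For the suppression analysis the same
statistic compares a condition's per-bin response against the pre-touch
baseline of the same trials. Condition B is measured on the *same 10 ms-bin
scale* as condition A: $\mu_B$ is the mean baseline bin rate and
$\sigma_B^2$ the mean across-trial variance of the baseline bins. Summarizing
the baseline by its 1.5 s mean instead would shrink $\sigma_B^2$ toward zero,
and any response bin that happens to contain no spikes would then produce a
large negative value; at realistic rates (a 4 sp/s unit leaves a given 10 ms
bin empty on every trial about 9% of the time) that artifact biases the whole
population series negative. Matching the measurement scale of the two
conditions removes it.

## Analysis windows

All windows are half-open `[start, end)` in seconds relative to the first
touch of a trial: baseline `[-1.5, 0)`, response `[0, 0.3)`, early
`[0, 0.05)` (feed-forward part of the response), late `[0.07, 0.3)` (where
suppression dominates), with 10 ms bias bins anchored at the touch (an edge
at 0). Bias bins are non-overlapping; "computed every 10 ms" with 10 ms
bins is the simplest consistent cadence and the bin width is configurable.

## Rates and z-scoring

Spikes are binned per unit and trial around the first touch; rates are
counts divided by the bin width. Z-scoring is per unit against the
baseline-window bin distribution pooled over *engaged* trials (Home-context
Hits and CRs, after the disengagement filter below). The reference is
deliberately shared across behavioral contexts so that Miss/Away effects are
expressed on the engaged scale and deltas are comparable across conditions.
The baseline SD is floored at 0.1 sp/s; near-silent units are flagged rather
than dropped, which keeps population histograms complete while marking
unreliable z-values.

## Unit classification

* **Responsive**: one-way ANOVA over three groups of per-trial rates
  (baseline, response to stimulus A, response to stimulus B) with Tukey
  post-hoc comparisons; a unit is responsive when baseline differs from
  either stimulus at p < 0.05. The A-vs-B contrast is not consulted —
  responsiveness means a tactile response to one or both whiskers, not
  selectivity.
* **Preference**: sign of the mean response-window bias (Hit- vs
  CR-preferring); exact zeros are flagged ties.
* **Touch effect**: paired two-sided t-test of response- minus
  baseline-window rates on CR trials at p < 0.05; the sign of the mean
  difference labels the unit facilitated or suppressed. All
  disengagement-filtered CR trials (both port positions) enter this test:
  the negative-stimulus response is the quantity under test and is not gated
  by the water port in the generative model, and restricting to Home CRs
  would halve the trial count under the alternating-block protocol.
* **Baseline firing rate** (bfr): mean rate in the 1.5 s before first touch
  over engaged trials; units can be partitioned by decreasing rate edges
  (e.g., `bfr >= 10`, `10 > bfr >= 5`, ...) with half-open intervals, so a
  unit at exactly 4.0 falls in the `>= 4` group.

**Disengagement filter.** Sated or disengaged animals stop licking
altogether. A maximal run of consecutive no-lick trials (Miss or CR) that
contains at least five Misses is treated as a disengagement window and the
CR trials inside it are removed. CRs inside the run count as members of the
window but not toward the five Misses. The rule is isolated in one function
(`filter_disengaged_cr()`) so alternative readings are one-line swaps; it
never removes licked trials and never reorders.

## Facilitation-suppression lag

Units facilitated and suppressed by the negative stimulus are compared by
cross-correlating, within each mouse, the trial-averaged z-scored CR
response of every facilitated unit with every suppressed unit over the
response window in 10 ms bins. The correlation is coefficient-normalized
(zero-lag autocorrelation of a trace with itself is 1) with zero-padding,
and the traces are *not* mean-removed: z-scored traces are already expressed
relative to the baseline mean, and demeaning a 300 ms all-response window
would push the late part of a facilitated trace negative and can relocate
the minimum to a spurious large positive lag (we measured exactly this
failure on synthetic sessions). The lag of the minimum correlation estimates
the temporal offset; negative lag means suppression follows facilitation.
Ties resolve to the smallest |lag|; constant-trace pairs are skipped and
counted. The correlation window is the 300 ms touch response (configurable).

## Behavioral-context modulation

Evoked (0-300 ms) and baseline (-1.5-0 s) rates are compared per unit
between Hit trials and either Miss trials (Home context) or Away trials
(positive-stimulus trials with the water port displaced) with a two-sided
Mann-Whitney U test at p < 0.05 (the sidedness is a documented choice; the
population-level change is additionally tested with a one-sample t-test of
the per-unit z-scored deltas). Trials are drawn as labeled; the first trial
after each Home/Away switch is not excluded.

**Occupancy matching.** Because run speed and whisker curvature can differ
between contexts, comparisons can be repeated on occupancy-matched trials:
the pooled joint feature space is binned (8 bins per feature by default,
joint rather than marginal binning — the stronger guarantee), each condition
is subsampled without replacement to the per-cell minimum, and statistics
are averaged over 20 independent resampling permutations. Matched joint
histograms are identical across conditions by construction, which the test
suite verifies on random fixtures.

## Reaction-time coupling

Per unit, the per-trial baseline-window rate on Hit trials is correlated
with the lick latency (first lick after first touch; trials without a
qualifying lick are excluded pairwise, not imputed). Pearson correlation is
the population default and Spearman is exposed as an option — the source
analyses name both for different panels, and the discrepancy is preserved
rather than resolved. The population of per-unit coefficients is tested
against zero with a one-sample t-test.

## Whisker kinematics

Tracked-label coordinates (4 labels per whisker at 500 fps, DeepLabCut-style
wide CSV with optional per-label likelihoods) are analyzed in image
coordinates: x right-positive, y down-positive. The whisker angle of a label
is the signed angle between the face-point-to-label vector and the image
vertical axis, so a label straight "above" the face point reads 0 degrees and
one along +x reads +90; with the face point behind the pad, protraction is
positive. The convention is documented rather than universal — the sign is
configurable by choosing the face point.

Whisker curvature is the Menger curvature (reciprocal circumradius,
$\kappa = 4A/(d_{12} d_{23} d_{31})$) averaged over all four 3-label
combinations per frame; collinear labels give exactly 0, frames with a
missing (low-likelihood) label give `NA`.

Touch detection segments the angle trace into whisk cycles at protraction
peaks (minimum prominence 5 degrees, minimum period 40 ms — covering the
10-25 Hz whisking envelope; both configurable) and reports, per cycle, the
first frame at which the tip label enters the surface ROI. Retraction-phase
entries are flagged but still reported; excluding those trials is left to
the caller. A tip that never leaves the ROI is a configuration error.

## The synthetic-session generator

The generator is first-class, tested code, and its defaults *are* the study
conditions the rest of the package is validated against:

* **Trial protocol**: 1.5 s stimulus windows, Hit/Miss/CR/FA labeling with
  reward contingent on licking, and Home/Away alternation after every 7
  positive-stimulus trials (Away trials cannot contain licks). Sessions
  default to 200 trials and 60 units.
* **Baseline rates** are log-normal (median 4 sp/s, log-SD 1), matching the
  heavy right tail of collicular and cortical populations.
* **Evoked responses** are inhomogeneous-Poisson spike trains (thinning on a
  1 ms grid; candidates drawn homogeneously at the grid maximum and accepted
  proportionally, which is exact for the discretized intensity). The
  preferred-stimulus response is a peak-normalized alpha-like kernel
  (onset 5 ms, rise 8 ms, decay 250 ms) with amplitude
  `1.5 x baseline + 5` sp/s; the non-preferred response is weaker and more
  transient (gain 0.25 SC-like / 0.15 S1-like, decay 60 ms).
* **Suppression** applies to positive-preferring units on negative-stimulus
  trials of the discrimination task, with onset delayed 60 ms (SC-like) or
  10 ms (S1-like) after facilitation onset, amplitude 0.9 x baseline
  (suppression depth scales with baseline rate, reproducing the
  baseline-rate-by-response interaction), and a sustained kernel (rise
  12 ms / decay 250 ms SC-like; rise 8 ms / decay 150 ms S1-like, i.e.,
  cortical suppression mirrors the facilitation dynamics while collicular
  suppression is delayed and sustained).
* **Context and readiness**: one engagement latent per trial scales baseline
  rates (log-gain 0.2), raises Miss probability when low, and shortens lick
  latency when high (`latency = 0.55 - 0.06 x engagement + N(0, 0.12)` s,
  clamped into the response window), which jointly produces lower baselines
  on Miss trials, a negative baseline-rate-to-latency correlation in every
  unit, and a >= 92% latency tail above 0.3 s. Miss and Away trials
  additionally scale the evoked response of positive-preferring units (0.5
  and 0.6) and Away scales their baseline (0.7); S1-like profiles leave the
  Away gains at 1.
* **Covariates**: AR(1) run speed (sharing the engagement latent) and
  curvature summaries per trial; whisk contacts at 10 Hz through the
  stimulus window, with the evoked kernel triggered on the first touch only
  (full adaptation; the `touch_adaptation` parameter re-enables responses to
  later touches).

All draws consume a single RNG stream in a fixed order (baselines,
preferences, stimuli, engagement, outcomes, latencies, covariates, touches,
then spikes unit by unit), so a `(config, seed)` pair reproduces a session
bit-for-bit. A ground-truth record (per-unit labels and kernel amplitudes,
per-trial latents) accompanies every session for recovery tests.

**Calibration.** The kernel shapes were calibrated once, jointly, so that on
default sessions (i) the population-mean CR bias relative to baseline of
positive-preferring units turns negative near 70 ms after touch and stays
negative through 300 ms, and (ii) the pairwise minimum-correlation lag
recovers the configured 60 ms / 10 ms suppression delays without estimator
bias — which requires the suppressed trace to be approximately a delayed,
negated copy of the facilitated trace, hence the shared sustained kernel
shape. Measured over five seeded sessions per region: pooled SC-like lag
-60.5 ms, S1-like |lag| 9.9 ms, zero-crossing at the 75 ms bin, latency tail
96%. The defaults were frozen after that calibration.

**What the generator does not emulate** — and hence what passing tests do not
show about real recordings: no correlated variability between units beyond
the shared engagement latent (real noise correlations are structured), no
bursting or refractoriness (renewal Poisson only), no adaptation across the
session, no responses to individual later touches under the default full
adaptation, no electrode drift or sorting errors, and behavioral covariates
that are only summaries, not full kinematic traces. Recovery results
demonstrate that the estimators measure what they claim under the stated
model, not that the model exhausts real data.

## Numerical and design choices

* Time is in seconds, zero-referenced to session start; per-trial alignment
  is computed on demand, never stored redundantly.
* All intervals are half-open, so bins partition time without double
  counting.
* Event-time lists inside trial CSVs are semicolon-delimited within a cell,
  keeping trials one row each; floating values are written with 17
  significant digits and re-parsed through `strtod`, so file round trips are
  bitwise exact.
* FA trials are retained at ingest and excluded per analysis — filtering is
  an analysis choice, not an ingest choice.
* Validation rejects invariant violations (unsorted spikes, outcome/lick
  inconsistencies, outcome/stimulus mismatches) naming the offending unit or
  trial; nothing is silently repaired.
* Kilosort/Phy sorted output is read from `spike_times.npy` /
  `spike_clusters.npy` with the sample rate taken from the `params.py`
  sidecar; a minimal NPY reader/writer for 1-D arrays is included.
* Degenerate statistics (zero-variance groups, constant traces, all-NA
  units) return flagged neutral values or are skipped and counted — never
  silently dropped.

## Problem sizes used in validation

The packaged checks run the full pipeline on five seeded 60-unit, 200-trial
sessions per region profile for the lag and zero-crossing recoveries, 15
sessions for the latency tail, and 2000 fabricated null units for the
type-I-error suites; these sizes give binomial/standard errors comfortably
inside the tolerances being checked while keeping a complete run in the
single-digit minutes.

## Worked example

```{r, eval = FALSE}
library(whiskerbias)

gen <- generate_session(generator_config(region_profile = "SC_like"), seed = 11)
session <- gen$session

classes <- classify_units(session)
population_preference_stats(classes[classes$responsive, ])

lag <- session_lag(session, classes = classes)
glance(lag)
autoplot(lag)

tensor <- rate_tensor(session)
ztensor <- zscore_tensor(tensor, session)
glance(condition_modulation(ztensor, session,
                            contrast = "Home_vs_Away", window = "baseline"))
glance(baseline_latency_correlation(tensor, session))
```

## Known limitations

The preference fractions printed by the source study (70% positive-preferring
in SC, 58% negative-preferring in S1, and so on) are properties of real
recordings; the generator reproduces the *mechanisms* (suppression-driven
bias, baseline-rate interactions, context gains) with configurable effect
sizes, not those exact fractions. Hit/FA rates at expert performance are
assumptions of the config, not published facts. The per-unit Mann-Whitney
tests are two-sided and the z-score reference is the engaged-trial baseline;
both are choices the provenance record logs so either alternative can be
reproduced.
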