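---
title: "Simulating and analysing fear-extinction psychophysiology with fearext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing fear-extinction psychophysiology with fearext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In differential fear conditioning, a neutral cue (the CS+) is paired with an
aversive outcome (here a 90 dB scream) while a second cue (the CS−) never
is; in extinction both cues are presented unreinforced, and the decline of
the differential response indexes safety learning. Individuals who score
high on Intolerance of Uncertainty (IU, a 27-item trait questionnaire)
show compromised extinction: the working hypothesis this package
operationalises is that low-IU individuals show a typical pattern (CS+ >
CS− early in extinction, no difference late), whereas high-IU individuals
generalize threat early (no CS+/CS− difference) and keep responding to the
CS+ late, while their CS− response falls from early to late.

`fearext` implements the full analysis chain as testable code: task design,
synthetic electrodermal/rating data with ground truth, skin conductance
response (SCR) scoring, learner classification, and the moderated
repeated-measures ANCOVA machinery, organised as an analysis workflow
(`analysis/01_simulate.R` … `05_calibrate.R`) over the package functions.

## Task design

`design_config()` encodes the paradigm: 24 acquisition trials (12 CS+, 12
CS−, 100% reinforcement), 32 extinction trials (16/16, unreinforced), and
an optional partial-reacquisition block that is generated but never
analysed. Trial timing is cue 1.5 s (sound 0.5 s after CS+ onset for 1 s),
blank 3.0–6.45 s, rating scale 4 s, blank 1.0–2.5 s.

Pseudo-randomization is by rejection sampling: permutations of the
condition labels are drawn uniformly until no more than three identical
conditions occur in a row; after 10,000 failed attempts a
constraint-infeasible error is raised. This makes the order distribution
uniform over admissible sequences — the simplest defensible choice given
that the original pseudo-randomization algorithm is not documented.
Whether the order was fixed across participants or drawn per participant
is likewise unknown; `simulate_cohort(shared_order = )` supports both,
defaulting to per-participant orders (the more conservative choice for
group-level inference).

## The synthetic cohort

The generator's defaults *are* the study conditions: 38 subjects,
questionnaire panels with IU M = 63.92, SD = 19.56 (range 27–135), STAIX-2
M = 44.02, SD = 9.33, PSWQ M = 51.60, SD = 11.56. Inter-instrument
correlations are not reported in the descriptives the generator emulates;
0.6 between each pair is assumed (configurable). Scores are drawn from a
latent multivariate normal whose location, scale and correlation are
pre-calibrated by a deterministic fixed-point scheme so that the delivered,
range-respecting scores carry the requested moments; out-of-range values
are redrawn from their exact truncated conditionals.

Each trial's SCR is a bi-exponential kernel
\(k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}\) (τ_rise = 0.75 s,
τ_decay = 2.5 s, unit peak; onset latency N(1.5 s, 0.3 s)) scaled by a
per-trial amplitude

\[ A = \max\{0,\; m_{\text{cell}} + b_{\text{cell}}\, z_{IU} +
  \varepsilon\},\qquad \varepsilon \sim N(0, 0.15\,\mu S), \]

zeroed with probability 0.33 (acquisition) or 0.53 (extinction). The
raw-scale cell means \(m\) and IU slopes \(b\) are solved numerically
(`calibrate_raw_mean()`, truncated-normal expectation via quadrature) so
that the *square-root-scale* magnitudes — the scale on which results are
reported — match the published cell table at mean IU (acquisition CS+ 0.79,
CS− 0.32; extinction early CS+ 0.32 / CS− 0.29, late CS+ 0.29 / CS− 0.22
√µS) and encode the moderation pattern at ±1 SD of IU. The default
sqrt-scale slopes are CS+ early 0, CS− early +0.03, CS+ late +0.05, CS−
late −0.03 per SD of IU: at z = −1 this gives an early differential with
equal late cells; at z = +1 equal early cells, a late differential, and a
CS− early-to-late drop. No raw-amplitude distribution is published; the
truncated-normal trial noise is an assumption of this package.

The continuous recording adds a 2 µS tonic level, a slow random-walk drift
(0.005 µS·s^−1/2), and white measurement noise (0.005 µS) at a default 50
Hz (the original hardware sampled at 1000 Hz; the scorer is
sampling-rate-agnostic and tested for 50-vs-250 Hz agreement, so the
desk-scale default trades nothing but disk and time). A schematic ~1.2 Hz
pulse channel exists solely so the conjunctive motion-artifact rule can be
exercised; cardiac realism is out of scope. Ratings are latent-normal
draws (cell mean + subject intercept SD 0.7 + trial noise SD 0.8), rounded
and clamped to the 1–9 scale; latent cell means are bias-corrected so the
post-rounding expectations equal the targets (acquisition CS+ 6.14, CS−
3.10; extinction early 3.12/2.41, late 2.28/1.86). Ratings carry no IU
moderation, matching the null rating findings the generator emulates.

One master seed spawns per-subject child streams, so subject *i*'s data do
not change when the cohort grows; cohort-level counterbalancing is the one
deliberately cohort-dependent quantity.

What the generator does *not* emulate — habituation within the early/late
blocks, US-evoked responses separable from CS-evoked ones (the 500 ms
CS–US interval makes them inseparable in the emulated design anyway),
respiratory/cardiac physiology, non-stationary tonic level — bounds what
green tests show: the pipeline recovers what this generative model
produces, not every property of laboratory electrodermal data.

## SCR scoring

`detect_scr()` implements event-related trough-to-peak scoring: the signal
is low-pass filtered (2nd-order zero-phase Butterworth, 2 Hz default);
candidate onsets are local minima of the smoothed signal falling 0–7 s
after CS onset; each rise is walked forward to the point where the
derivative turns negative or stays below 0.001 µS/s for 0.2 s
("flattening out"), capped at 10 s after the SCR onset or the next CS
onset, whichever comes first; amplitude is the trough-to-peak difference
with a 0.03 µS minimum, below which the trial scores zero. The peak may
fall after the 7 s window provided the onset is inside it. When several
rises qualify, the *first* in-window onset is scored (stimulus-locked
reading; `response_selection = "largest"` is available). Because the
zero-phase filter smears rises slightly backwards in time, reported onset
latency is refined to the 5%-of-amplitude upward crossing.

Two interpretive choices deserve note. The flattening criterion and the
peak-search cap are this package's operationalisation of a manual scoring
rule; both are exposed in `scoring_config()`. And with inter-cue intervals
as short as ~9.5 s, a response tail can still be decaying at the next
trial's onset; clipping the peak search at the next CS onset is the
package's resolution of an ambiguity the emulated protocol leaves open.

Motion artifacts require a high-pass residual exceeding a robust z of 6 in
*both* the electrodermal and pulse channels inside the trial window
(conjunctive rule); with no pulse channel the rule cannot apply and no
trial is flagged (with a warning) rather than falling back to a
single-channel rule the design explicitly avoids. The pulse residual uses
a higher cutoff (4 Hz) than the electrodermal one because the pulse wave
itself carries ~1.2 Hz content that a 2 Hz residual would misread as
noise floor.

The first trial of each phase is excluded, amplitudes are square-root
transformed, and cell magnitudes average the transformed values *including
zeros* over usable trials; extinction cells are the first 8 vs last 8
trials per condition by presentation order. The same early/late split is
applied to ratings, since one Time factor serves both measures; rating
reduction applies no first-trial exclusion (that rule is specific to SCR).

## Learning assessment

The conditioned-response score is the mean of the first two usable CS+
extinction trials minus the first two CS− trials, per measure. "Usable"
means post-exclusion for SCR (configurable to first-two-presented). A
subject is a non-learner only if both scores are ≤ 0 — a score of exactly
0 counts as no differential response, a boundary that is measure-zero for
continuous SCR and matters only for tied integer ratings. Non-learners
are flagged and retained by default (`drop_non_learners` inverts this).
Under the default calibration the early-cell differential is small
(0.03 √µS at mean IU), so roughly 86% of simulated subjects classify as
learners — a clear majority, though below the ~92% the emulated study
observed, whose first extinction trials plausibly carried a larger
differential than the early-block average this generator uses.

## The moderated RM-ANCOVA

For the 2×2 design, each subject contributes four cell values and the
model is fitted through orthogonal per-subject contrast scores:

* G = mean of the four cells,
* C = condition effect, T = time effect, X = interaction,

each regressed on the mean-centered moderator. The squared t of a
regression's intercept is the F of the within-subject effect; the squared
t of its slope is the F of the effect × IU interaction; the between-subject
IU effect comes from the G regression. All tests are on (1, n−2) df —
exactly the classical repeated-measures ANCOVA with one continuous
covariate, but in a form that a brute-force least-squares oracle can check
line by line (the test suite does, to 1e−8, and the acceptance script
re-derives it). The acquisition phase fits the same machinery without the
Time factor. Sums-of-squares type is moot for single-df, single-covariate
contrast regressions. A constant covariate degenerates gracefully: the
within tests collapse to one-sample t's (df n−1) and moderation effects
are reported as NA.

Simple-slopes contrasts (CS+ vs CS− within each time half; early vs late
within each condition) are estimated from the whole-sample fit evaluated
at IU = mean ± 1 SD, with standard errors from the coefficient covariance
and the SD recomputed per analyzed subsample (ratings and SCR samples
differ after exclusions). p-values are two-sided and uncorrected,
mirroring the reporting conventions the package emulates. Effect size is
partial η² = F/(F + df2) for df1 = 1. Hierarchical regressions enter
STAIX-2 and PSWQ in step 1 and IU in step 2; ΔR² is the step increment
with F-change = ΔR²(n−k₂−1)/((1−R²₂)(k₂−k₁)); standardized β comes from
the z-scored refit; collinear designs raise a rank-deficiency error
naming the offending columns.

The subject exclusion screen mirrors the emulated taxonomy: non-responders
(no non-zero usable extinction SCR), excessive movement (artifact fraction
above 25%), and an optional |z| > 6 outlier screen on the early CS+ − CS−
difference score (off by default in simulation, where the generative model
produces no such outliers).

## Calibration studies

`run_calibration_study()` repeatedly simulates cohorts at the *cell* level
(`simulate_cell_magnitudes()` draws per-trial amplitudes from the same
effect model and reduces them with the same sqrt/zero-inclusion rule,
skipping waveform rendering) and refits the ANCOVA. With all IU slopes
zeroed, the Condition × Time × IU rejection rate estimates the type-I
error (nominal 0.05; 2,000 cohorts of n = 34 in `analysis/05_calibrate.R`
and the acceptance script). With the default model, 500 cohorts measure
how often the qualitative sign pattern is recovered. "Recovered" is
sign-based, decided before any measurement: low-IU early contrast > 0 and
greater than its late value; high-IU late contrast > 0 and greater than
its early value; high-IU CS− early−late > 0. Significance-based recovery
was rejected as an operationalisation because the emulated early-extinction
contrast sits near p = 0.05, where replicate-level significance is a coin
flip and the criterion would measure power noise rather than pattern.

## Problem sizes and numerical choices

The shipped scripts use 38-subject cohorts at 50 Hz, 10,000 seeds for the
run-length property, 2,000 replicates for type-I error and 500 for pattern
recovery — sizes at which every Monte-Carlo tolerance in the test suite is
several standard errors wide. Calibration roots are solved to 1e−10
(`uniroot`), truncated-normal expectations by adaptive quadrature to
1e−10 relative tolerance. Ties in learner classification go to
"non-learner" (literal reading of "no differential response"). Empty
magnitude cells drop the subject with a logged reason rather than
silently; every exclusion appears in the run log.

## Known limitations

Cohort-level F statistics of the original study are not reproducible — its
raw data are not public — so correctness rests on analytic identities,
design constants, ground-truth recovery and calibration properties. The
artifact detector is tuned to the schematic two-channel transient the
generator injects; real movement artifacts are more varied. The effect
model is linear in z(IU) by construction; curvature in the true moderation
would be invisible here. Overlapping responses closer than the minimum
~9.5 s cue spacing are resolved by window clipping, not deconvolution —
continuous decomposition methods are explicitly out of scope.
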