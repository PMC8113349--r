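---
title: "Models and methods in delaydecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in delaydecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaydecode)
```

`delaydecode` analyzes trial-based data from head-fixed delayed-response
licking experiments: a mouse hears a click train whose rate (six
log-spaced values between 20 and 125 clicks/s) instructs a left or right
lick, must withhold its response over a variable delay (uniform on
0.3–1.5 s), and responds after a go cue.  Trials with premature licks
are violations and excluded from analysis; response time (RT) is the
interval from go cue to first lick.  The package covers the complete
quantitative chain for such experiments — behavior, perturbation
statistics, two-photon calcium imaging, population decoding, fiber
photometry, and slice physiology — and ships a synthetic-data generator
with known ground truth so every stage is testable without animal data.

## Behavioral model

Choice behavior is summarized by the four-parameter sigmoid

$$P(\text{lick right}) = y_0 + \frac{a}{1 + e^{-(x - x_0)/b}},$$

with $x = \log(\text{click rate})$, inflection $x_0$, slope scale $b$,
lower bound $y_0$, and upper bound $a + y_0$.  `fit_psychometric()`
fits this by bounded weighted least squares on the per-rate choice
proportions, which has the same minimizer as least squares on the
per-trial binary responses.  Because the surface is multimodal in
$(x_0, b)$, five dispersed starting points are tried and ties broken by
residual sum of squares; bounds keep $y_0 \in [0,1]$, $a \in [0,1]$ and
$b > 0$ (the stimulus–response mapping fixes the slope sign).  An
all-one-side responder makes $(x_0, b)$ unidentifiable; that case is
detected and returned as a flagged degenerate fit with $a + y_0$ equal
to the observed proportion rather than as an optimizer failure.

Session metrics follow the task's conventions: accuracy is computed over
scored (correct/error) trials only, violation and miss rates over all
trials, and RT summaries use medians over correct trials.  Delay-resolved
curves use four equal-width bins over 0.3–1.5 s; the binning is a
display choice, not part of the task definition.

`compare_conditions()` implements the paired design used for
chemogenetic experiments: per session pair, differences in error,
violation and miss rates (means) and in RT (medians), tested across
pairs with a two-sided sign-flip permutation on the mean paired
difference.  Resampling p-values use add-one smoothing,
$(k+1)/(n+1)$, so a p-value of exactly zero is never reported.

## Perturbation choice models

The effect of optogenetic or chemogenetic inactivation on choice is
quantified on the logit scale.  `normalized_ipsi_bias()` subtracts each
session's mean control P(lick ipsi) from the ipsilateral-choice
indicator of every inactivation trial and aggregates trials across
sessions (positive values mean more ipsilateral choices).
`fit_choice_logistic()` fits logistic models of choice on normalized
log click rate plus perturbation terms: Model 1 with additive
inactivation-epoch and inactivation-region effects, Model 2 adding
three-way epoch × region × difficulty interactions, where difficulty is
$1 - \text{(normalized log rate)}^2$.  The normalization maps the six
log rates onto $[-1, 1]$ centered on the midpoint of the log range; the
scale constant is exposed because other conventions exist.

Subject random effects are approximated by fixed per-subject intercepts
with cluster-robust (by subject) covariance.  This is a deliberate
deviation from a full generalized linear mixed model: it is
deterministic, has no convergence failures on separation-prone
perturbation designs, and for the questions asked here (fixed-effect
contrasts) gives very similar inference; exact mixed-model estimates are
not a goal of the package.  Complete separation is detected from the
fitted probabilities and handled by a ridge-stabilized Newton refit,
reported as such.  Nested models are compared with a likelihood-ratio
test, and families of coefficient contrasts are adjusted by the
single-step max-|z| method: simulate from the multivariate normal
implied by the fit's covariance (100,000 draws by default, seeded) and
report $P(\max_j |z^*_j| \ge |z_i|)$.

## Imaging preprocessing

Raw ROI fluorescence is corrected for slow drift by subtracting a
centered rolling percentile: the 8th percentile over 400 frames (about
14 s at 30 Hz) for two-photon data, the 5th percentile over 1000 frames
for 20-Hz photometry.  Edge windows are truncated rather than reflected
so no values are fabricated; the kernel is implemented in C++ and is
tested against a per-frame brute-force oracle.  ΔF/F is
$(F - F_0)/F_0$ with $F_0$ the histogram mode of the corrected trace
(Freedman–Diaconis bin width, reporting the mean of the values in the
fullest bin — a continuous trace has no mode without a density
estimate, and the within-bin mean keeps the estimate inside the data's
support and exactly scale-equivariant).  A nonpositive $F_0$ is an
error naming the ROI rather than a silent division.

Because delay and response durations vary across trials, responses are
epoch-averaged rather than time-locked: the 0.5-s stimulus window
(sound), exactly the final 500 ms before the go cue (delay), go cue to
first lick (response), and 1 s after the first lick (lick; the span of
this last window is a package default, configurable).  Each trial's mean
pre-sound ΔF/F is subtracted first.  For delays shorter than 500 ms the
delay window necessarily overlaps the stimulus tail; such trials are
kept but flagged by default, with an option to exclude them, since the
task's specification does not resolve this case.  Dendritic-trunk and
soma ROIs are treated identically.

## Selectivity and decoding

The "0.5th percentile of 1000 shuffles" has no unique definition; the
null interval uses type-6 quantiles, which place the bounds at the
$(B+1)p$-th order statistics and make the interval's coverage exact
(the interpolation used by other quantile types sits inside the tail
and inflates the false-positive rate to roughly 1.5%).

Single-ROI selectivity uses the rank-based area under the ROC curve,
$P(a > b) + \tfrac12 P(a = b)$, oriented so 1 means contralateral (or
high-rate) preference; correct and error trials are both included for
choice labels.  Significance comes from shuffling trial labels 1000
times: an ROI is selective if its AUC leaves the shuffled 0.5–99.5
percentile interval in any epoch (a per-epoch empirical p is also
returned for the conventional p < 0.05 display threshold).  Shuffles are
seeded per ROI from a session seed so partial or parallel runs
reproduce.  Epoch-wise AUC distributions are compared with a paired
permutation test on the mean AUC difference (5000 swaps); the test
statistic is exposed as a choice because the functional is not uniquely
determined by convention.

Population decoding uses an L2-regularized linear maximum-margin
classifier (cost 1) on epoch-averaged ΔF/F, without per-feature
standardization.  The training matrix is divided by a single global
factor — its overall standard deviation — before fitting: ΔF/F units
are arbitrary per session (the mode-based $F_0$ sets the scale), so
this pins the meaning of cost 1 to the data's own scale while leaving
the relative geometry of the features untouched.  For cross-validated accuracy, 90% of trials
are sampled for training (majority class subsampled so training classes
are exactly balanced — asserted, not assumed) and the rest scored, 100
times; the chance control shuffles labels and repeats the identical
procedure.  Leave-one-out decoding classifies each trial from all
others and yields the per-trial 0/1 outcomes used to model RT: trials
are binned at RT quintiles within 0–2.5 s per session, and accuracy is
correlated with RT both across pooled session-bins and across session
means of the bins, because the pooling convention is ambiguous —
both are reported.  The RT mixed model (`fit_rt_lmm()`) regresses
per-trial RT on delay and the leave-one-out outcome (optionally
performance, tongue and nose positions) with subject random effects by
maximum likelihood; a singular random-slope covariance triggers a logged
fallback to random intercepts.

## Photometry

The isosbestic (410-nm) channel captures motion and hemodynamic
artifacts but not calcium.  After slow correction of both channels, the
410 signal is regressed onto the 470 signal and the fitted control
subtracted.  The residual of that regression is mean-centred, which
would make a mode-based $F_0$ nonpositive; the package therefore
subtracts only the mean-centred fitted control, preserving the 470
baseline level.  All downstream photometry statistics are AUC-based and
therefore invariant to this per-trace affine choice.  Choice-selectivity
time courses use 150-ms centered bins on 3-frame-smoothed,
baseline-subtracted trial traces, aligned to delay onset or first lick;
in delay-aligned analyses every sample after a trial's own delay offset
is masked.  The early epoch is the sound period; the late epoch is
1–1.5 s after delay onset, computed over trials whose delay reaches the
window start with post-delay samples masked, and undefined when no trial
reaches it.  A session is "consistent" when early and late AUC prefer
the same side of 0.5 (an AUC of exactly 0.5 counts as inconsistent, and
is logged).  Cell types are compared by an uncorrected 2×2 Pearson
chi-squared on consistency — the uncorrected statistic is the one that
reproduces the package's worked example, and a corrected variant is
available by flag — and by both a two-sample F test and a permutation
test on the early-AUC variance, because the appropriate variance test
for this comparison is a design choice; both are reported under their
own names.

## Slice responses

A cell is responsive when, on the trial-averaged 10-pulse train, more
than 40% of pulses (strict inequality) evoke a depolarization exceeding
3 s.d. of the baseline voltage (1 s before the first pulse, measured on
the averaged trace) within 50 ms of light onset.  Reliability is the
fraction of single-pulse sweeps crossing the same criterion against
their own per-sweep baselines — mirroring the distinction between
averaged-trace detection and per-trial reliability.  Latency is the
first threshold crossing of the mean trace after light onset and
amplitude the maximum voltage change within 50 ms; hyperpolarizing
deflections are not counted as transients.  Whether the 40% criterion
counts pulses within one averaged train or across repeated trains is
config-exposed; the averaged-train reading is the default.  Note that
threshold-crossing latency is biased late by a fraction of the EPSP
rise time whenever noise is non-negligible; the estimate is within one
sample of truth only in the low-noise limit.

## The synthetic-data generator

The generator emulates the study's data structure under its stated
conditions: six log-spaced click rates on 20–125 Hz, uniform 0.3–1.5-s
delays, a 3-s response window, violations whose hazard rises
logistically with delay (the rising shape is observed; the logistic form
is a modeling choice), and RTs that decline linearly with delay —
defaults (intercept 0.597 s, slope 0.099 s/s, noise s.d. 0.1 s) mirror
the observed decline of mean RT from roughly 0.57 s to 0.45 s across
the delay range.  Calcium dynamics use a double-exponential kernel with
$\tau_{rise} = 0.2$ s and $\tau_{decay} = 1.5$ s, typical for GCaMP6s
and configurable.  Membrane noise in the slice generator is an AR(1)
process with a 5-ms correlation time: synaptic background noise is
autocorrelated, and this is what makes "any crossing within 50 ms"
a meaningful detection criterion (white noise at 10 kHz would make it
trigger constantly).

Choice selectivity is injected on event amplitudes, not on ΔF/F, so the
preprocessing chain is genuinely exercised: per-epoch amplitudes are
Gaussian with a choice-dependent mean separation
$\sqrt{2}\,\Phi^{-1}(\text{AUC})$ per the equal-variance Gaussian AUC
identity.  Because the indicator kernel is slow, an event in one epoch
bleeds into later windows; the generator compensates by computing, per
trial, the exact kernel gain of every event on every epoch window
(including the pre-sound baseline window that is later subtracted) and
solving for the impulse amplitude that realizes the target window
response given the carryover of earlier events.  Ground-truth AUC
targets therefore describe the epoch responses the pipeline actually
measures.  Two residual real-data effects remain, deliberately: sensor
noise and drift attenuate measured AUC slightly, and the rolling
percentile baseline is itself signal-correlated in sessions dense with
transients, which attenuates later-epoch selectivity by roughly 0.05–0.1
at a 0.9 target.  The tests account for this by checking the clean sound
epoch at the tight tolerance and later epochs at looser ones.

What the generator does not emulate: correlated noise across ROIs,
non-Gaussian amplitude distributions, bleaching trends beyond a slow
sinusoid, lick artifacts in photometry, or realistic video (keypoint
traces only).  Passing tests therefore demonstrate correctness of the
analysis chain under the stated generative assumptions, not robustness
to every artifact of real recordings.

## Numerical choices and problem sizes

Permutation and bootstrap p-values use add-one smoothing and are exact
(full enumeration) when the number of label assignments is at most 200.
The acceptance checks run at desk scale: chance-level decoding uses one
session of 40 ROIs and about 200 scored trials with 20 shuffle
repetitions of 100 resamples; null coverage uses 500 simulated neurons
with 1000 shuffles each; calibration checks use 1000 replicates of
small-n tests.  These sizes were chosen so the whole suite completes on
a single CPU in minutes while leaving Monte-Carlo error well inside the
stated tolerances.

## Known limitations

Fixed-intercept plus cluster-robust inference approximates, but does
not replicate, crossed random-effect logistic models.  The
threshold-crossing latency estimator is biased late at realistic noise.
The across-session bootstrap for movement divergence is anticonservative
with very few sessions (with three sessions, an all-same-sign
configuration already reaches the resolution floor); analyses should use
about eight sessions, as the tests do.  The ΔF/F division by a mode
near zero after percentile subtraction amplifies the trace scale; all
selectivity and decoding statistics used downstream are invariant to
per-ROI affine transforms, so this affects display scale only.
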