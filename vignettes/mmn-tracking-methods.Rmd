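---
title: "Tracking MMN and P3a across repeated oddball blocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking MMN and P3a across repeated oddball blocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The mismatch negativity (MMN) is the brain's automatic change-detection
response: a frontocentral negative deflection of the event-related
potential (ERP) elicited when a rare "deviant" tone interrupts a stream of
identical "standard" tones, typically followed by a P3a positivity
indexing involuntary attention capture.  Because the MMN survives
inattention and even unconsciousness, it is used at the bedside as a
prognostic marker in coma.  A core practical difficulty is that component
detectability fluctuates — within a patient, a response can wax from
easily detectable to undetectable between recording blocks taken hours
apart — so a single snapshot can mislead.  `mmntrack` implements the full
analysis chain needed to study this: a synthetic multi-deviant oddball EEG
generator with explicit block-level presence control, ERP preprocessing,
two statistical detection routes (permutation and Bayesian), per-block
presence tracking, and a group-level habituation analysis.

Because no public recordings accompany this design, the generator is a
first-class, tested module: every downstream claim is exercised against
data whose ground truth is known by construction.

## The simulated paradigm

One recording block contains `n_tones = 2400` tones at a regular
`soa_ms = 450` stimulus onset asynchrony: 82% standards and 6% each of
duration, frequency and intensity deviants (counts fixed by
`round(n * p)`, any rounding remainder going to standards, so block
composition is deterministic: 1968/144/144/144).  Deviant order is drawn
uniformly over all arrangements in which at least one standard separates
any two deviants (a switch disables the constraint); the placement scheme
samples one "gap" of a standard backbone per deviant, which makes every
admissible arrangement equally likely.  Each standard immediately
following a deviant is tagged, so analyses can exclude post-deviant
standards if desired (they are included by default).

ERP templates are additive Gaussian pulses on a six-channel frontocentral
montage (F3, Fz, F4, C3, Cz, C4, unit gain).  Standards carry an
obligatory N1 (peak 100 ms, -2 µV).  Deviants add *deviance components* on
top of the standard response:

| condition | components (peak ms, amplitude µV, SD ms) |
|---|---|
| duration  | MMN (205, -3, 22), P3a (300, +3, 35) |
| frequency | DRN (105, -1.45, 22), P3a (290, +2, 35) |
| intensity | DRN (105, -3.07, 22), P3a (290, +2.2, 35) |

Design notes on these defaults:

* Because deviant = standard + deviance, the noiseless difference wave
  equals the configured deviance components exactly, which gives every
  downstream stage an analytic oracle.  The separate N1 latency shift of
  real duration deviants (~150 ms) is deliberately not modelled — it would
  enter the difference wave and break that contract.
* Pulse widths of 22 ms (negativities) and 35 ms (P3a) keep the MMN and
  P3a lobes from displacing each other's rendered peaks by more than one
  sample, and correspond to realistic deflection widths (~50-80 ms at
  half maximum).  Much wider pulses would smear the components into one
  another.
* Amplitudes reproduce the reported ordering and spacing of deviant
  window means: over the export windows the duration-frequency and
  intensity-frequency marginal differences are about -1.27 µV and
  1.3 µV.
* Real frequency/intensity deviants show their P3a earlier (180-230 ms)
  than duration deviants; the generator places all P3a pulses inside the
  250-350 ms analysis window so that the synthetic pipeline is
  self-consistent.  This is a deliberate simplification.

Noise is `epoch = (1 + jitter) * (obligatory + gain * deviance) + pink +
white`, with white noise SD 4 µV and pink (1/f power) noise SD 6 µV per
sample and channel, independent across channels, and 20% multiplicative
trial amplitude jitter.  Pink noise is spectrally shaped white noise
(amplitude ∝ f^-1/2, DC removed, rescaled to the target SD).  The
`block_presence_gain` in [0, 1] scales deviance components only — gain 0
makes deviant trials statistically identical to standards.  This is the
waxing/waning control.  At the study level, each subject carries a
deviance amplitude factor drawn as N(1, `subject_amplitude_sd`); with the
default 0.6 the programmed standardized group effect of any
deviance-component window mean is 1/0.6 ≈ 1.67, in the range of reported
group effect sizes for these components (≈1.3-2.3).  All randomness flows
from one root seed through deterministic sub-streams (`derive_seed`), so
every dataset is bit-reproducible.

What the generator does **not** emulate: spatially correlated noise and
volume conduction (channels are independent, so ROI averaging gains a full
√6), ocular and muscle artifacts (threshold rejection is exercised with
injected spikes instead; ICA correction is left to external tools),
latency jitter and drift, and a realistic 64-channel topography.  Passing
tests therefore demonstrate statistical correctness of the machinery, not
field-realistic effect sizes for real recordings.

## Preprocessing

The chain is filter → baseline → reject → average:

* **Band-pass** 0.1-30 Hz, 4th-order Butterworth applied forward-backward
  (zero phase; implemented as a vectorised two-pass IIR filter, verified
  against its specified frequency response: ±5% at 10 Hz, ≥20 dB down at
  50 Hz).  Because all stages are linear, the band may equivalently be
  applied to epochs, to ROI trial series, or to evoked series; the
  pipeline uses whichever is cheapest at the point of use.
* **Baseline correction** subtracts each trial's and channel's mean over
  -100-0 ms.
* **Artifact rejection** flags trials whose peak-to-peak amplitude exceeds
  200 µV (configurable) on any channel; flagged trials are excluded
  everywhere downstream and the per-condition counts are logged.
* **Averaging** produces one evoked response per condition and block,
  recording how many trials entered.

Epochs span -100 to 600 ms at `sampling_rate_hz` (default 512 Hz;
sample k sits at -100 + k·1000/rate ms).

## Detection

All statistics operate on the unweighted mean of the six frontocentral
ROI channels.

**Serial permutation t-tests with Tmax correction.**  At every sample a
one-tailed t statistic compares deviant against standard: paired across
subjects' evoked responses at the group level (t on the difference
waves), independent across trials within a subject (Welch t by default,
given the ~1968-vs-144 imbalance; a pooled-variance switch exists).  The
null distribution is built from 1000 resamples — random sign flips of
difference waves (paired) or random relabelings preserving group sizes
(independent) — recording per permutation the most extreme signed
statistic in the tail direction across the *entire epoch* (the family can
be narrowed via `tmax_window_ms`).  Corrected p-values use the add-one
rule `p = (1 + #extremes ≥ t_obs) / (B + 1)`, so p ≥ 1/(B+1) and the
family-wise error rate is controlled over the whole epoch.  Exact ties
between permuted and observed statistics are counted as extreme under a
1e-9 relative tolerance, so results do not depend on floating-point
evaluation order.  An exhaustive mode enumerates all 2^n sign patterns
for small paired designs.  Two one-tailed passes are run per deviant:
negative for the MMN, positive for the P3a.

**Peaks and effect sizes.**  The component peak is the most negative
(MMN, searched 80-230 ms, covering both the early fused
deviant-related negativity and the later duration MMN) or most positive
(P3a, 250-350 ms) point of the ROI difference wave; ties resolve to the
earliest latency.  Cohen's d is computed on window-mean amplitudes over
50 ms and 100 ms windows centred on the peak (clipped at epoch bounds
with a flag): paired, `mean(diff)/sd(diff)`; independent, difference of
means over the pooled SD.  Plain d carries the classical small-sample
inflation (≈5% at n = 17), so the bias-corrected Hedges g is returned
alongside and used when comparing against a programmed effect.  Zero
variance yields signed infinity with a warning flag.

**Bayes factors.**  Per-sample BF10 values come from the t statistic via
the unit-information (BIC-approximation) Bayes factor,
`BF10 = (1 + t²/ν)^(n/2) / √n`, which equals
`exp((BIC_H0 - BIC_H1)/2)` for the nested mean models and is monotone in
|t| at fixed n.  A JZS alternative (Cauchy prior on the standardized
effect, configurable scale) is provided; the two agree in ordering.  The
exact prior of the original flat-prior implementation is not documented
beyond its name, so the BIC form is offered as a transparent default, not
asserted as identical.  Window maxima are classified by the
Lee-Wagenmakers cut-offs (1-3 anecdotal, 3-10 moderate, 10-30 strong,
30-100 very strong, >100 extreme; lower bounds inclusive; BF < 1 favours
the null).

**Presence decisions.**  Permutation-present requires at least
`min_duration_ms = 10` of contiguous corrected-significant samples
(run length × sample period) intersecting the component window — the
minimum suppresses single-sample flukes and can be set to 0.
Bayes-present requires the window maximum BF10 ≥ 3 (the "moderate"
threshold; whether anecdotal evidence should count as presence is left
configurable because the original tables do not say).  Manual-visual
calls can be merged from annotation CSVs and must carry an annotator tag.
One ledger row per subject × block × deviant × component × method feeds
the detection-rate tables and the +/- report grid (Bayes cells show
+ to ++++ for anecdotal through very strong/extreme).

## Habituation analysis

Mean difference-wave amplitudes are exported per subject × deviant ×
block over ±50 ms around the group-average peaks (180-230 ms duration
MMN; 80-130 ms frequency/intensity), then analysed with a two-way
within-subject ANOVA (deviant × block, subject as random factor) on
complete cases only (listwise deletion, dropped subjects logged; 13
complete subjects give the reference deviant df of (2, 24)).  The engine
is `car::Anova` on a multivariate linear model; Greenhouse-Geisser ε is
computed from the error SSCP of orthonormal polynomial contrasts (so it
is available even when error df are scarce), both uncorrected and
GG-corrected p-values are always reported, and partial eta squared is
`SS_effect / (SS_effect + SS_error)`.  When the deviant effect is
significant, Bonferroni-corrected pairwise t-tests compare deviant
marginal means averaged over blocks; the sign convention (first-named
minus second-named level) is stated in the output because the original
report leaves it ambiguous.  An independent brute-force sums-of-squares
oracle (Helmert contrasts, direct SS computation) checks F, df, ε and
ηp² in the test suite.

## Numerical and scale choices

* Degenerate inputs: identical condition data give t = 0 (not NaN) and
  F = 0 with p = 1; all-rejected conditions stop the pipeline with an
  error naming the condition and block.
* Monte-Carlo suites run at reduced problem sizes chosen for statistical
  margin per unit compute: the null false-positive rate uses 200
  simulated blocks of 240 tones at 200 Hz; group power and effect-size
  recovery use full 2,400-tone blocks at 125 Hz (full trial counts keep
  the residual-noise deflation of the recovered effect below ~2%);
  waxing/waning recovery uses 500-tone blocks at 200 Hz, where the
  per-block single-subject test has essentially full power at gain 1 and
  a ~1% false-call rate at gain 0.  The full 512 Hz, 2,400-tone paradigm
  is exercised in the composition checks and available everywhere.
* Fixture I/O uses Feather (Arrow) plus a JSON sidecar and round-trips
  bit-losslessly; EDF(+) and BrainVision readers/writers are minimal,
  self-contained implementations for epoching real recordings around
  event markers.

## Known limitations

Single-subject detection rates depend strongly on deviant trial counts
and the noise model, so the synthetic single-subject rates are not
calibrated to the published per-subject tables (which derive from human
EEG that is not available); what the tests pin down is false-positive
control, power at programmed effect sizes, and the recoverability of
block-to-block fluctuation.  ICA-based ocular correction, cluster-based
correction, source analysis and decoding are out of scope.
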