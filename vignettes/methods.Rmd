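---
title: "RT-band-limited choice probability in the C1: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-band-limited choice probability in the C1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(c1readout)
```

This vignette documents the scientific models behind `c1readout`: what the
synthetic-data generator assumes, how each analysis stage is defined, the
numerical conventions, the design choices that were genuinely open, and what
the package's passing tests do and do not establish about real data.

## The question and the analysis logic

The C1 component of the visual evoked potential (~80–90 ms) indexes initial
afferent V1 activity; its polarity inverts between upper- and lower-field
stimulation and its amplitude scales with contrast. In a two-alternative
contrast comparison between an upper- and a lower-field grating array, the
difference in the two arrays' C1 contributions is therefore a scalp-level
read of the physical evidence. *Choice probability* asks whether, with the
physical stimulus held constant, residual trial-to-trial fluctuations of
this signal still predict the upcoming choice. For a transient signal the
prediction is sharper: any choice dependence should occupy an intermediate
band of response times — absent for responses emitted before the signal's
information can reach the decision stage, and diluted at slow responses by
evidence accumulated from later processing. The analysis chain in this
package quantifies exactly that: single-trial C1 amplitudes enter logistic
models of choice alongside every other choice-predictive covariate that a
comprehensive search can find, RT dependence is modelled by quadratic RT
interactions and by sliding RT-percentile windows, and the RT band's edges
are estimated with a bootstrap over participants.

## The synthetic observer

No equations for the data-generating decision process are published, so the
generator specifies one: the simplest mechanism we found that reproduces all
of the behavioural and electrophysiological regularities the analyses rely
on. It is a one-dimensional bounded accumulator with two evidence stages:

* a **transient early sample** delivered once at `early_latency` (80 ms):
  `early_gain * (ev + eps)`, where `ev` is the (saturated) signed contrast
  difference and `eps ~ N(0, early_noise_sd)` is trial-unique sensory noise
  that is *shared with the simulated C1 amplitude*. This shared noise is the
  generative source of choice probability: given the stimulus, C1 and choice
  co-fluctuate only through `eps`;
* a **sustained drift** from `late_latency` (150 ms):
  `late_gain * (ev + eta)` per second, with a per-trial drift perturbation
  `eta` and within-trial diffusion;
* a **collapsing bound** reaching zero at `deadline - motor_delay_mean`, so
  a response is always produced near the deadline;
* **Gaussian start-point variability** (`start_sd`), which produces
  chance-level fastest responses and errors that are no slower than correct
  responses, and a **start-point bias away from the previous choice**
  (`history_bias`), which produces a switching bias concentrated at fast
  RTs;
* a **Gaussian motor delay** (100 ± 20 ms) between bound crossing and the
  recorded response.

Evidence passes through a saturating transform `sat * tanh(ev / sat)` with
`sat = 0.12`: cortical contrast responses saturate, and without this the
high-contrast easy blocks (differential contrast 0.30) would be decided by
the early sample alone, with response times near 180 ms and no
post-latency accumulation for the CPP analyses to work with. With
saturation, easy-block responses remain near ceiling accuracy at realistic
~300 ms response times.

Default parameter values were fixed once, while designing the generator, to
reproduce the study conditions the analyses assume: overall accuracy
titratable to ~55%; mean RTs of roughly 240 ms and 320 ms under the 400 and
600 ms deadlines; a conditional accuracy function that starts at chance,
peaks at an interior RT and declines for the slowest responses; and a
switching bias strongest in the fastest RT quintile. The concavity of the
conditional accuracy function arises from the interplay of start-point
variability (fast guesses), the early sample plus drift (rising accuracy),
and the collapsing bound selecting low-drift trials at slow RTs.

## Stimuli and session structure

Each trial presents two 9 x 9 grating arrays whose grand mean contrast is
exactly 60%; the target array is incremented and the other decremented by
the differential contrast `dc` (plus a signed `bias` term applied toward or
against the target, symmetrically, so the grand mean is preserved). Within
each array the per-grating deviations are a fixed multiset (nine values
spanning ±20% in 5% steps, each appearing nine times), shuffled within each
polar-angle column, so jitter sums exactly to zero on every trial and the
physical evidence never varies within a difficulty level. The easy blocks
(dc = 0.30) exceed the displayable range at the jitter extremes; gratings
are clipped into [0, 1] there and array means recomputed, so exact mean
conservation is an invariant only of the non-clipping configurations. The
default session structure per deadline is 10 blocks of 120 trials with
targets balanced (600 trials per target location and deadline), preceded by
a 160-trial easy block and a 160-trial single-array block.

The automated difficulty titration emulates the experimenter-in-the-loop
staircase: 24 simulated blocks of 240 trials alternate between deadlines; a
multiplicative staircase with a decreasing (stochastic-approximation) gain
sweeps `dc` on accuracy error, while `bias` is nudged against choice-rate
imbalance. Rather than stopping at the first lucky block — which biases the
result toward the side the staircase approached from — the routine fits a
weighted logistic psychometric curve of block accuracy on `log(dc)` over the
whole history, interpolates the `dc` at the target accuracy, and confirms
with a 1,200-trial run. Across seeds the validated accuracy falls within
about one percentage point of the 55% target.

## The EEG forward model

Scalp data are built from unit-normalized 2-D Gaussian spatial patterns on
a schematic 128-channel layout (concentric rings, A/B/C/D banks; positions
only define electrode pools and neighbourhoods, not real geometry). For
injection, each pattern is rescaled so its peak channel has weight one, so
amplitude parameters are in microvolts at the peak electrode regardless of
montage size. Components per trial:

* **C1**: a raised-cosine transient centred at 85 ms on the *difference* of
  the lower- and upper-field C1 patterns (which have negative inner product
  and a slight topographic shift, giving the difference a positive and a
  negative pole). Its source amplitude is
  `c1_gain * (lower - upper contrast) - shared_noise_gain * eps` plus a
  small modulation congruent with the previous choice (`history_c1_gain`,
  0.15 µV) — the latter injected independently of the behavioural switching
  bias and in the opposite (choice-congruent) direction, as a target for the
  C1-as-dependent-variable analysis;
* **CPP**: a centro-parietal ramp starting at `late_latency`, with slope
  `0.015 + 0.25 * |ev_saturated|` µV/ms (so easy ≈ 0.045 and hard ≈ 0.025
  at the defaults, peaking at roughly 3–7 µV), peaking at the response and
  decaying afterwards;
* **alpha**: 10 Hz activity over left/right occipital patterns whose
  pre-stimulus amplitude is reduced over the hemisphere contralateral to
  the upcoming choice (the attention-like, choice-predictive covariate the
  signal search should find), with per-trial random phase and a
  post-stimulus envelope decay;
* a common (choice-independent) P1/N1 complex; and
* **background noise**: spectrally shaped Gaussian noise with 1/f power
  plus an ongoing mid-band (theta) bump at 6 Hz, 5 µV RMS per channel. The
  theta component matters: real EEG carries substantial ongoing power
  between the artifact-screening bands, and without it the (0–3)/(3–7) Hz
  and (20–40)/(3–7) Hz band-power ratios are so volatile on clean data that
  the screening thresholds produce ~8% false flags; with it, below 1%.

Artifacts (blinks with a frontal topography and a vertical-EOG signature,
single-channel low-frequency drift, single-channel 22–38 Hz muscle bursts)
are injected on request with ground-truth labels, and per-trial gaze
summaries are attached.

What the generator deliberately does **not** emulate: volume-conduction
from a realistic head model, spatially correlated noise, non-stationary
artifacts, eye-movement time series (gaze enters only as per-trial
summaries), electrode drift across blocks, or individual differences in
component topography beyond what noise induces. Passing recovery tests on
these data therefore demonstrate the *estimators'* correctness under the
stated generative assumptions, not robustness to everything real data can
do.

## Preprocessing conventions

All latencies are in milliseconds, sample indices are 0-based, epochs are
half-open `[t0, t1)`, and the aligning event sits exactly on a sample at
time 0 (the span start snaps to the nearest sample: at 512 Hz the
target-locked epoch runs from −599.6 ms and contains exactly 512 samples).
The baseline window (−50 to 30 ms, endpoints inclusive) is subtracted per
trial and channel; baseline correction is idempotent.

The acquisition low-pass is a 77-tap windowed-sinc FIR. Only two response
landmarks of the original design are published — a −3 dB corner of 35.3 Hz
and 83.5 dB attenuation at 50 Hz — and attenuation that deep in a 77-tap
raised-cosine design only occurs near a spectral null, i.e. the design
parks a null on the mains frequency. `reconstruct_lowpass()` recovers the
nominal cutoff by a 0.01 Hz grid search minimizing the worst relative
deviation from the two landmarks jointly, and reports both landmarks from
the single reconstructed filter (cutoff 37.93 Hz; corner 35.25 Hz,
83.1 dB at 50 Hz). Two raised-cosine tapers are available. The default is
the 0.54/0.46 taper: within the 77-tap family at 512 Hz it is the only one
whose mains-frequency null co-occurs with a corner at 35.3 Hz (the 0.5/0.5
taper's null design corners at 35.8 Hz); the 0.54/0.46 taper is also what
several standard FIR design tools apply by default under a loosely-used
"Hanning" label. Filtering is applied with group-delay compensation and
reflective padding, so event latencies are preserved.

Artifact screening applies the study's fixed thresholds (blink: |vEOG| >
40 µV with 50 ms padding; drift: (0–3)/(3–7) Hz power ratio > 5; muscle:
(20–40)/(3–7) > 2; absolute voltage > 50 µV; baseline range > 40 µV; full
rejection for stimulus-coincident blinks, saccades, or median gaze
deviation > 1°). Band powers are single-taper periodogram sums over bins
whose centres fall in the half-open band; the DC bin is excluded from the
drift band, since a constant offset is not drift. Channel-level flags
exclude a channel only from analyses whose measurement window overlaps the
flagged segment. Channel repair, where requested, is an inverse-distance
weighted average of the four nearest montage neighbours — a deliberately
simple scheme; spherical-spline interpolation is out of scope.

## Feature extraction

C1 measurement electrodes are chosen per participant from the easy block:
the target-location difference topography (lower minus upper) in 80–90 ms
is ranked within a posterior pool, and the `k = 4` most positive and most
negative electrodes form the two poles (the count is configurable; the
original study's per-participant counts are unreported). The single-trial
C1 is the bipolar mean difference over the window, positive for
lower-favouring evidence; trials whose poles are fully artifact-flagged are
missing, not errors.

The STFT uses 400 ms rectangular windows (205 samples at 512 Hz) at 25 ms
steps snapped to the sample grid, with magnitudes divided by half the
window length so a sinusoid at a bin frequency reads out its amplitude;
analysis frequencies are the 12 non-zero bins up to 30 Hz.

The choice-signal search operationalizes what was originally a visual
inspection, so its thresholds are deliberately liberal (p < 0.05
uncorrected, ≥ 20 ms, ≥ 2 electrodes): false positives cost little when the
found signals are only used as covariates, while false negatives would
undermine the mediation argument. Per participant, activity is averaged by
choice and subtracted; group t-tests across participants define candidate
clusters contiguous in time; in the time-frequency domain, clusters at
adjacent frequencies merge when their time windows and electrode sets
overlap with Jaccard index ≥ 0.5. A cluster whose difference topography has
both poles is split into one signal per pole before the retention t-test —
aggregating a lateralized difference across both hemispheres would cancel
it.

## Choice models

Binary variables are coded 1 for upper-field targets and choices, correct
responses and the 600 ms deadline. Continuous predictors are z-scored over
the included trials, pooled across participants (a per-participant
alternative is not provided for z-scoring, but is for the window
percentiles); RT enters in seconds, uncentered, with collinearity handled
by the pruning operation when requested. Trials are excluded for artifact
rejection or RT > 600 ms, with listwise deletion for missing covariates.
With quadratic RT interactions every predictor contributes three
regressors, so the full model — C1, target location, previous choice, seven
time-domain and six time-frequency signals — has 48 regressors plus
intercepts. Random intercepts per participant use the Laplace approximation
(`lme4`); the sliding-window models omit them by design, since window-level
trial counts per participant become unbalanced at the RT extremes.

The internal logistic fitter is Fisher-scoring IRLS on the normal equations
with warm starts between adjacent windows; the test suite verifies
agreement with `stats::glm` to well below 1e−6 on fixed data. Wald
statistics are reported as t with residual degrees of freedom (the
reporting convention of the original is not stated beyond large-sample t
values; with tens of thousands of observations the distinction from z is
immaterial).

Sliding windows span 20 percentile points of the pooled included-trial RT
distribution, centred at every unit percentile from 10 to 90 (81 windows);
each window's centre in ms is the median RT of a ±0.5-percentile
neighbourhood. The C1 coefficient is sign-flipped for reporting so positive
values mean choice-congruent C1 amplitude.

## Onset and offset estimation

A window sequence of significant/non-significant outcomes is modelled as a
single unbroken run of significant windows; the fitted run maximizes
agreement with the observed flags, the empty run competing on equal
footing. Ties are broken toward higher agreement, then longer runs, then
earlier starts — the tie-break is not specified in the original and is a
documented package decision, chosen for determinism and contiguity. Run
edges are converted to latencies at the linearly interpolated
zero-crossings of the coefficient series nearest before the run start and
after the run end, falling back to the run-edge window centres when no
crossing exists. The bootstrap resamples participants with replacement
(trials kept intact within participant), rebuilds the windows from each
sample's own pooled RT distribution, refits the run, and reports medians
and 2.5/97.5 percentile intervals; samples with an empty run contribute no
latency and are counted rather than imputed. The study-scale default is
10,000 samples; the package's tests use 100–500, which is enough for
medians and coarse intervals. Above-chance accuracy uses the same machinery
with an intercept-only logistic model per window, flagged significant only
when accuracy is above chance.

## CPP slope analysis

Response-locked epochs (span [−600, 100) ms, a package decision covering
pre-response buildup and the peak) are re-cut from target-locked data; the
source epochs must extend far enough past stimulus onset to cover
`RT + 100 ms`, which is why the pipeline simulates [−600, 700) and crops to
[−600, 400) for target-locked analyses. Pre-stimulus baselines are applied
before response-locking. The CPP electrode is the centroparietal-pool
channel with maximal mean amplitude from −150 to −50 ms. Slopes are
ordinary least squares over 50 ms windows stepped by 10 ms on each
participant's condition-average waveform; easy vs hard blocks are compared
by a one-sided paired t-test per window (easy steeper, α = 0.05).

The onset of evidence-dependent buildup is the earliest window that is
significant and remains significant in every window up to the peak of the
grand-average easy waveform — restricted to windows lying fully before the
peak, because at the peak both conditions' slopes pass through zero by
definition and the contrast vanishes there. The response-locked onset is
converted to a stimulus-locked latency by subtracting its magnitude from
the mean RT of the contrasted trials.

A genuine limitation, verified in simulation: the response-locked contrast
convolves the stimulus-locked divergence with the RT distribution, so with
realistic RT spreads (SD ≳ 50 ms) the detected onset can shift by tens of
milliseconds depending on statistical power — which is consistent with the
wide bootstrap intervals this estimator produces on real data. The
package's recovery validation therefore uses a controlled dataset with a
narrow RT spread (SD 10 ms, 18 participants, 100 trials per condition, full
montage), under which the estimator recovers a 150 ms divergence to within
a few milliseconds; tests at wider spreads are used only to characterize
the smearing, not to assert accuracy.

## Decoding

Per participant and 10 ms window, a linear discriminant on per-channel mean
amplitudes is trained and evaluated on the same trials — matching the
original protocol, so absolute accuracies are inflated by overfitting and
the meaningful reference is the empirical chance curve from label-shuffled
refits (default 100 shuffles; the original count is unreported). Because
128 channels with few trials make the sample covariance singular, the
pooled covariance is shrunk toward a scaled identity,
`(1 - λ) S + λ mean(diag(S)) I` with λ = 0.2 by default; the original's
regularization is not stated. Real vs shuffled accuracy is compared per
window by a one-sided paired t-test across participants.

## Reproducibility and formats

Every generator is bitwise-reproducible under a fixed seed; pipeline stages
derive their seeds from a global seed plus a stage-name hash, so stages can
be re-run independently. Epoch containers are versioned directories (JSON
metadata plus a flat little-endian float64 array) with an explicit error on
unknown versions; trial tables are CSV; signal definitions and onset
estimates are JSON; model and window tables are TSV. Outputs carry the
configuration hash and seed, and identical configurations reproduce
byte-identical tables.

## Problem sizes used in the tests

The suite validates at reduced, stated scales chosen to keep each property
sharply testable: the band-edge recovery of the sliding-window pipeline
runs at the study's trial scale (18 participants × 1,200 trials, 500
bootstrap samples) because the windowed regressions are cheap on tabular
covariates; EEG-level checks (artifact screening, C1 selection, signal
search, CPP recovery, decoding) use 6–18 participants with 40–200 trials
each and montages of 16–128 channels; null calibrations use 40–200
replicates at small n. The full 10,000-sample bootstrap and
2,400-trial-per-participant session are available through the same
functions by changing arguments.
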