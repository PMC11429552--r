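---
title: "Band-limited EEG features and the classification of haptic feedback trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited EEG features and the classification of haptic feedback trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticEEG)
```

## The problem

When a person performs a simulated motor task (here the reference paradigm
is a simulated drilling task), the presence or absence of force feedback
leaves a signature in the EEG. `hapticEEG` implements a complete pipeline
for finding and exploiting that signature in epoched, labeled EEG:

1. restrict to nine frontal/central/parietal channels
   (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4);
2. decompose each 2 s epoch into four bands — low alpha (8–9.5 Hz), high
   alpha (10–13 Hz), low beta (13–21 Hz), high beta (21–30 Hz);
3. per channel and band, compute ten features: Hjorth activity
   (variance), mobility and complexity; Welch band power; permutation
   entropy; spectral entropy; Higuchi fractal dimension; rescaled-range
   Hurst exponent; skewness; excess kurtosis — 360 features per epoch;
4. rank features by a maximum-relevance / minimum-redundancy (MRMR)
   quotient, optionally followed by a Mann–Whitney U filter;
5. train a battery of seven classifiers (SGD, SVC, decision tree, Gaussian
   Naive Bayes, KNN, random forest, MLP) over nested feature subsets on an
   80/20 shuffle split with grid-searched hyperparameters;
6. summarize per-channel class means for topographic display.

The real recordings behind the reference paradigm are not publicly
released, so the package ships a synthetic EEG generator that emulates the
study conditions — 15 participants, 100 haptic + 100 non-haptic trials
each, 1024 Hz — and *plants* class effects of known identity, direction and
size. Everything downstream can therefore be validated by recovery: the
selection stage must find the planted features, the classifiers must reach
accuracy consistent with the planted separation, and a null configuration
must stay at chance.

## The synthetic generator

Each epoch and channel starts as `1/f^beta` colored noise (default
`beta = 1`, a typical broadband EEG slope), synthesized by spectrally
shaping white Gaussian noise: the FFT of a white draw is multiplied by a
real, even gain `f^(-beta/2)` and inverted, so the random phases come from
the white draw and the whole generator is bit-reproducible under its seed.
Small per-participant, per-channel amplitude offsets (±10% by default)
emulate pooled-subject heterogeneity.

A `planted_effect` perturbs exactly one named `Channel_Band_Feature` cell
through one of three mechanisms:

* **band_gain** — the in-band spectral component of the higher class is
  multiplied by `1 + magnitude`; this drives variance (activity) and Welch
  band power.
* **burst_amplitude** — one Gaussian-windowed band-limited burst
  (envelope SD 25 ms, random center, carrier and phase) is added per epoch
  of the higher class, with amplitude `magnitude` times the background
  in-band RMS; sparse large excursions drive excess kurtosis.
* **slope_tilt** — a power-preserving change of the in-band *shape*. For
  spectral-entropy targets the lower class's in-band spectrum is
  concentrated by a Gaussian bump (narrower effective bandwidth, lower
  entropy). For Hurst targets the higher class's in-band component is
  amplitude-modulated by a slow (0.25–2 Hz) lognormal envelope, which
  lengthens its temporal persistence and raises the rescaled-range
  exponent while leaving the expected band power unchanged.

The split realization of `slope_tilt` is a deliberate design decision. We
measured the response of the R/S Hurst estimator on 2 s band-limited
epochs to pure within-band spectral reshaping and found it saturates near
a standardized mean difference of d ≈ 1.0 — short epochs simply do not
expose enough spectral leverage — while spectral entropy responds to the
same knob several times more strongly. One spectral knob therefore cannot
realize d ≈ 1.5 on both features at the same cell. Envelope modulation is
an independent, nearly power-neutral lever on temporal persistence, and
with it each feature family has its own knob.

### Calibration

`magnitude` has different units per mechanism, so the package carries
empirical magnitude-to-effect-size response curves (measured on 600-epoch
single-effect runs at the default settings, frozen as tables) and inverts
them by interpolation when an effect is given only an `intended_d`. The
**strong** preset plants the ten features of the reference class contrast
— low-beta Hurst at Pz, Fz, Cz, P4; high-beta kurtosis, band power and
variance at Cz; low-beta spectral entropy at C3, Cz, Pz; non-haptic higher
everywhere except C3 spectral entropy — at d ≈ 1.5 each (the **moderate**
preset targets d ≈ 0.6). Where two planted features share a physical knob
the preset compensates: the two Cz high-beta gains split one gain and
leave room for the power the kurtosis bursts add, and at Cz/Pz low beta
the envelope and concentration knobs are each reduced for the other's
cross-contribution. `verify_manifest()` fills in realized Cohen's d per
planted effect so every run can audit what was actually achieved; on the
default conditions all ten land in roughly [1.2, 1.9].

Side effects are physical and intentional: bursts add band power, envelope
modulation adds heavy-tailed amplitude structure (so kurtosis at modulated
cells also separates), concentration nudges Hurst. Effects are local to
their channel, but within a perturbed channel/band cell several of the ten
features may move together — as they would in real EEG. What the generator
does **not** emulate: event-related dynamics within the epoch, blink/EMG
artifacts, volume-conduction correlations between channels, or non-trivial
participant covariance. Passing tests on this synthetic analog show the
pipeline's statistics and plumbing are sound, not that real haptic EEG is
classifiable at the same accuracy.

## Numerical choices

* **Filtering** — 4th-order Butterworth band-pass applied forward and
  backward (zero phase, effective 8th order). The response is realized by
  multiplying the FFT of odd-reflect-padded epochs with the filter's
  squared magnitude response, which equals forward–backward filtering up
  to boundary treatment and vectorizes across thousands of epochs. Padding
  is three low-cutoff periods.
* **Welch PSD** — 1 s Hann segments, 50% overlap, one-sided density; the
  band-power scalar is the *mean* density over in-band bins (comparable
  across bands of different width). Spectral entropy normalizes the
  in-band density to a probability vector and divides the Shannon entropy
  by `log(#bins)`.
* **Permutation entropy** — order 3, delay 1, natural logarithm, ties
  broken by index order; the bound is `log(3!) ≈ 1.7918` nats.
* **Higuchi FD** — `kmax = 10`, least-squares slope of log mean curve
  length versus `log(1/k)`, clamped to the theoretical [1, 2] with a
  degeneracy flag rather than silent alteration.
* **Hurst** — classic rescaled-range estimator over a dyadic window ladder
  (16 … n/2, or from 8 for short signals), block-mean R/S, log–log slope,
  clamped to [0, 1] with a flag. The estimator accepts signals down to 32
  samples so that short-instance oracle checks are possible, although EEG
  use always runs at 2048 samples.
* **Moments and variance** — population (÷N) convention throughout;
  kurtosis is *excess* (Fisher) kurtosis, so Gaussian background sits at 0
  and the planted contrast's sign reads directly.
* **Degenerate inputs** — constant signals return defined values
  (activity 0, mobility/complexity 0, Hurst 0.5, FD 1, entropies 0) with
  flags, never exceptions, so a dead channel cannot abort a 108 000-signal
  extraction.

## Feature selection

`mrmr_rank()` is greedy forward selection: the first pick maximizes the
one-way ANOVA F statistic against the label; each later pick maximizes
`F(x) / mean |Pearson r(x, selected)|`. Ties break by column order and
constant columns rank last with score 0. The *reported* score is the
running minimum of the greedy quotient rescaled to a maximum of 100:
the raw quotient is not monotone in rank (a late, weakly relevant but
utterly unredundant feature can post a large quotient), while the reported
relevance of a ranking is conventionally non-increasing; both numbers are
kept in the result.

`mwu_filter()` applies a two-sided Mann–Whitney U test per candidate and
keeps `p < alpha` (default 0.05, uncorrected — the hybrid proposal is
deliberately a raw-p screen; a Benjamini–Hochberg flag exists for
methodological honesty). Class sizes up to 8 use exact permutation
enumeration with midranks, larger samples the normal approximation with
tie and continuity corrections. `select_features(method = "mrmr_mwu")`
filters the MRMR top-20 (the candidate pool size is configurable; 20
matches the ranking depth the reference analysis reports) and orders the
survivors by ascending p.

## Classification

`grid_train()` is an exhaustive grid search by mean 5-fold cross-validated
accuracy computed on the training partition only; features are z-scored
with statistics from each fold's training part, and the final model is
refit on the full training partition with its own scaler. The split is a
plain seeded shuffle (not stratified, matching the emulated protocol; a
stratified flag exists). Default grids: SGD (hinge/log loss, three L2
strengths), SVC (rbf/linear, three costs, three gammas), decision tree
(three depths, two leaf sizes), Gaussian NB (two variance smoothings), KNN
(k in 3/5/9/15, euclidean or manhattan), random forest (100/300 trees, two
depth caps), MLP (one hidden layer of 50, 100 or 25 units — the upstream
two-layer (50, 25) variant maps to its 25-unit bottleneck since the `nnet`
backend is single-layer — two decays, 500 iterations). All grids are
overridable per `model_spec()`.

Pooling epochs across participants into one shuffle split mirrors the
emulated protocol but shares participants between train and test, which
can inflate accuracy on real data; for real recordings a
leave-one-participant-out split should be preferred (the split seed and
per-class counts are recorded in the report to keep this auditable).
One consequence is worth stating plainly: when features are selected on
the full table before splitting — as the emulated protocol does — a small
optimistic bias flows into test accuracy. The package's null-control test
therefore selects features on the training rows only, which is the
leakage-free protocol; with no planted effects all seven classifiers then
sit inside the 45–55% binomial band at 600 test epochs.

## Problem sizes used by the tests

The test suite regenerates everything from code: a full-size strong-preset
dataset (3000 epochs, seed 42) shared across the acceptance checks, a
same-size null dataset, four additional 990-epoch strong runs for the
selection-recovery property (a *harder* recovery test than the full size,
since power only drops), 1000 short varied signals for the printed-bound
sweeps, and sub-second toy tables for the structural tests. The
monotone-information property (mean battery accuracy at 10 features ≥ at
5) is checked on the moderate preset, where accuracy is far from ceiling;
at the strong preset both subset sizes saturate near 99.8% and the
comparison would be a coin flip on sampling noise rather than a statement
about information.

## Known limitations

* The epoch length (2 s) is a configurable stand-in; the emulated paradigm
  does not pin down a latency window relative to trial onset.
* The generator's class effects are stationary across the epoch; no
  event-related time-locking exists, so time–frequency methods would see
  nothing the band summaries do not.
* The filter family, Welch segmentation, permutation-entropy parameters
  (beyond the `log(3!)` bound) and Higuchi/Hurst estimator details are
  explicit package choices; published analyses of this kind rarely print
  them, and other defensible choices would shift absolute feature values
  (not the class contrasts).
* MRMR here is the F-statistic/Pearson-correlation quotient variant;
  mutual-information variants are out of scope, as are wrapper/embedded
  selectors, deep-learning baselines, artifact rejection and
  re-referencing.
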