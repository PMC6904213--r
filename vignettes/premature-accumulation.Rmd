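---
title: "Premature evidence accumulation under temporal uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Premature evidence accumulation under temporal uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In most laboratory perceptual-decision tasks the observer knows exactly when
the informative evidence will arrive. `premacc` targets the harder, more
natural case: a two-alternative discrimination in which a subtle sensory
change (a contrast step between overlaid gratings, or the onset of coherent
dot motion) occurs after an unpredictable foreperiod of 800, 1200 or
1600 ms. Under that uncertainty, observers may begin accumulating
"evidence" before any informative signal exists. The package provides the
full measurement pipeline for that phenomenon — stimulus generation, motion
energy, EEG preprocessing, spectral and time-domain decision-signal
metrics, behavioural summaries, and the repeated-measures statistics — plus
a generative model that simulates behaviour and 128-channel EEG so that
every stage of the pipeline can be validated against ground truth.

## The variable-onset accumulator

Behaviour is generated by a single signed decision variable with two
absorbing bounds. Its defining feature is the *endogenous onset time*,
anchored to stimulus onset rather than to the sensory change:

$$ t_{on} = \beta_0 + \beta_1\,(FP_{n-1} - \overline{FP}) + \varepsilon,
   \qquad \varepsilon \sim \mathcal N(0, \sigma_{on}^2) $$

From $t_{on}$ the decision variable integrates
$\gamma\,e(t)\,dt + \sigma(t)\,dW$, where $e(t)$ is the physical evidence
(signed contrast difference, or the opponent motion-energy trace of the
trial's own kinematogram) and $\sigma(t)$ is the diffusion noise. Before
the sensory change $e(t)$ carries no signal, so any accumulation during
the foreperiod is noise (or, in the dot-motion task, genuine stimulus
fluctuations) — this is what produces premature build-up, premature
responses, and chance-level accuracy for responses near the change.

Key modelling choices, and why:

* **A single signed variable with two bounds**, not a race. It matches the
  target/non-target difference framing of the sensory readout
  (the d-SSVEP) and of Mu/Beta lateralisation, and keeps closed-form
  checks available (with zero noise, the crossing time is
  $bound/(\gamma e) + motor$, which the tests assert).
* **The sequential effect acts only on onset time** ($\beta_1 > 0$: a
  longer previous foreperiod delays the onset). This reproduces faster
  responses and larger pre-evidence build-up after short previous
  foreperiods, while leaving the build-up *rate* untouched — onset, not
  rate, carries the history effect.
* **A small temporal-attention lapse component**
  (`onset_lapse_rate = 0.04`): on a lapse trial the onset is drawn
  uniformly up to 5000 ms, often beyond the trial's end. Lapses are the
  model's source of missed responses, and because short-foreperiod trials
  end sooner, miss rates fall with foreperiod — the observed gradient —
  without any extra machinery.
* **Pre-evidence noise is attenuated** (`pre_evidence_noise_frac`,
  default 0.45): the pre-change sensory representation carries less
  variance than the stimulus-driven one. This keeps premature-response
  rates in a realistic range while still producing measurable
  pre-evidence build-up.
* **Fixed bounds by default.** An optional linearly collapsing bound
  (`bound_collapse`) implements deadline urgency, but it defaults to 0:
  in simulation it suppresses the miss rate to near zero (diffusion
  noise against a falling bound all but guarantees a crossing) and it is
  not needed for any of the signatures the analyses measure. With the
  default, the zero-noise crossing time has the exact closed form the
  tests assert.

Default calibration: with the titrated contrast step (0.055 per grating)
the drift-to-noise ratio yields roughly 65–70% accuracy among completed
decisions — the level the staircase procedure targets — mean decision
times of ~500 ms, premature rates rising steeply with foreperiod
(≈0.1% → ≈4.5% → ≈17%) and miss rates falling with it (≈5% → ≈3%).
These defaults are the package's study conditions; analysis scripts and
tests do not re-tune them.

## The forward EEG model

`synthesize_eeg_trial()` maps the hidden accumulator path onto reference-
free 128-channel EEG (BioSemi-style labels on a nominal sunflower montage;
the geometry is a documented stand-in adequate for spatial weighting,
neighbour interpolation and cluster bookkeeping):

* centro-parietal build-up `cpp_gain * |DV(t)|` on a Pz-centred Gaussian
  map, decaying after the response;
* 20/25 Hz oscillations on an Oz-centred map with amplitude
  `ssvep_gain * contrast(t)` per grating, with the task's per-trial
  phase-reversal counterbalancing modelled as a random sign (so the tags
  cancel in trial averages, as in recordings);
* 10–30 Hz narrowband noise on C3/C4 maps whose envelope
  desynchronises in proportion to the decision variable's excursion
  toward the chosen bound, more contralaterally than ipsilaterally;
* 1/f-like sensor noise (leaky-integrated white noise plus a white
  floor), and blink/channel-pop artifacts at configured rates, with
  blinks dominating the bipolar EOG.

What the generator deliberately does **not** emulate: volume-conduction
physics and realistic head geometry, CSD-transformable reference
structure, eye-movement (as opposed to blink) artifacts, inter-subject
topographic variability, line noise, and non-stationary alpha. Passing
tests therefore demonstrate that the pipeline measures what it claims to
measure on signals with the assumed statistical structure — not that the
biological signals obey that structure.

## Pipeline conventions and numerical choices

* **Filtering**: 0.05–35 Hz band limit, linear detrend, average
  reference. The low-pass is a zero-phase windowed-sinc (185 taps at
  512 Hz; >40 dB down at 50 Hz, computed from the coefficients in the
  tests). The high-pass is a zero-phase forward–backward 2nd-order
  Butterworth, because a windowed-sinc at 0.05 Hz would need more taps
  than an epoch has samples.
* **Epochs**: stimulus-aligned from 0 to foreperiod + 2000 ms;
  response-aligned −1000 to +600 ms; every epoch baselined to its own
  500–550 ms post-stimulus mean, computed in the stimulus frame for both
  alignments.
* **Artifacts**: trial rejection at |EOG| > 200 μV or any scalp channel
  > 100 μV within the stimulus-aligned epoch; channel interpolation
  (inverse-distance neighbour average) when a channel's own artifact
  count exceeds 10% of trials, capped at 10% of channels; subject
  exclusion above 40% trial loss. The rules are applied in that order, so
  interpolation rescues trials a bad channel would otherwise cost.
* **STFT**: 400 ms rectangular segments every 50 ms, labelled by median
  time. At 512 Hz a nominal 400 ms window is 204.8 samples; segments use
  205 samples and the DFT is evaluated at the nominal 2.5 Hz bins, which
  preserves the stated resolution and the integer-cycle property (8
  cycles at 20 Hz, 10 at 25 Hz) to well under 1%. Magnitude is divided by
  half the window length in samples so a sinusoid reads out its own
  amplitude.
* **SSVEP SNR**: tag-bin amplitude over the mean of the two bins each
  side, excluding the other tag frequency (and harmonics) from the noise
  set.
* **Mu/Beta**: 10–30 Hz band average excluding the 20 and 25 Hz bins,
  baselined at the 550 ms segment; lateralisation is contralateral minus
  ipsilateral to the response hand.
* **Measurement windows**: pre-evidence amplitude −50..+50 ms and slope
  −250..+50 ms around the sensory change; pre-response amplitude
  −150..−50 ms and slope −500..−200 ms (the Methods-stated window; the
  −450..−150 ms variant is available as an argument); N2 amplitude
  200–300 ms post change. Slopes are closed-form OLS, checked against the
  normal equations in the tests.
* **Cluster selection**: data-driven top-k channels within broad
  candidate sets around Pz/Oz/C3/C4/P7/P8 (k = 4, except 3 per N2 site),
  with polarity appropriate to each signal and label-order tie-breaks.
* **Outliers**: single-pass ±3 SD rejection on the pre-response measure,
  computed independently per signal.
* **Onset estimation**: first time the trial-averaged cluster waveform
  exceeds twice its baseline-span SD *sustained for 100 ms* — the sustain
  requirement stops single-sample noise excursions from counting as
  onsets. Recovery against ground truth is assessed within each
  previous-foreperiod level separately: the sequential onset shift makes
  the pooled trial average a mixture whose rise time reflects only its
  earliest component, so the pooled estimate is biased early by
  construction, not by estimator error.
* **Motion energy**: the classical opponent construction — fourth-order
  Cauchy quadrature pair (σ = 0.35°) × Gaussian (0.05°) in space, damped
  polynomials of order 3 and 5 with k = 60 s⁻¹ in time. These constants
  are conventions of the standard reference implementation, stated in
  `me_filter_params()`, not task facts; energies are unit-bearing only
  relative to the rasterisation grid (0.05 deg/px by default, 0.1 deg/px
  in the trial-level analyses for speed). Temporal filtering is causal
  with zero-padded history so the trace covers every frame; the start-up
  frames are flagged. The implementation is verified against a
  brute-force triple-loop convolution oracle.
* **rm-ANOVA**: orthonormal-contrast within-subject decomposition for 1–2
  factors, Mauchly's W with the first-order chi-square approximation, and
  Greenhouse–Geisser ε applied whenever Mauchly's p < 0.05. F values are
  verified against both a hand-computed sums-of-squares oracle and base
  R's `aov()` Error-stratum fit; the Mauchly p agrees with
  `stats::mauchly.test` to ~10⁻³ (base R adds Box's second-order series
  term).

## Open choices the source left under-determined

* The gratings-task aperture is described with an inner radius larger
  than its outer radius; the generator uses a full 6° disc, and no
  analysis depends on the aperture geometry.
* On–off versus counterphase flicker is not stated; flicker is modelled
  as on–off luminance modulation, carried as a state vector that does not
  affect contrast energy.
* Pseudorandomisation is implemented as foreperiod balance within blocks
  of 3·k trials (k = 1 by default).
* Accuracy is the percentage of **all** trials on which the direction
  was correctly reported — premature responses and misses count against
  it. The alternative (conditioning on correct/error trials only) turned
  out to carry a selection artifact: excluding premature responses
  removes precisely the noise-driven fast guesses, so cells with heavy
  pre-evidence noise have their measured accuracy *flattered* by the
  exclusion, and accuracy becomes U-shaped in noise exposure rather than
  monotone. The all-trials definition makes mistimed accumulation cost
  accuracy the way it costs the observer points. Mean RT pools corrects
  and errors. Premature responses with a recorded choice do enter the
  conditional accuracy functions (as the fraction of choices matching
  the target), whose earliest long-foreperiod bins are exactly where
  chance-level responding shows up. The sequential RT comparison on
  long-foreperiod trials is computed over **all** responded trials:
  premature responses carry real response times, and conditioning them
  away would bias a contrast whose driver is the premature-response
  process itself.
* The dot speed of the kinematogram is not reported; 5 deg/s is the
  package default and every motion-energy analysis states it.

## Problem sizes

The test-suite and the acceptance script run the EEG pipeline at 300
trials (the size at which onset recovery to ±100 ms is asserted),
behavioural simulations at 27,000 trials (sequential and congruency
contrasts are sub-percentage-point effects), the motion-energy checks at
single-trial scale, and the type-I-error calibration at 2,000 simulated
null datasets of 12 subjects. The analysis scripts use 5,400 gratings
trials (18 simulated subjects of 300 trials) and 240 dot-motion trials.

## Known limitations

Sequential effects are modelled through onset timing alone; real data
likely mixes onset, attention and criterion adjustments. The congruency
advantage in accuracy is a sub-1% effect in this model and is resolvable
only in large simulations. The nominal montage supports neighbour
interpolation but not source-space reasoning. The Exp-1 flicker-induced
left bias is available (`start_bias`) but defaults to 0; none of the
packaged analyses depend on it.
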