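---
title: "Morphological footstep detection from floor vibrations: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological footstep detection from floor vibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seismogait)
```

## The measurement problem

A person walking across a floor injects a short broadband vibration
burst at every initial contact of a foot. Geophone-based seismographs
on the floor record these bursts superimposed on low-frequency
building noise (sway, machinery, thermal drift) and white sensor
noise. Clinically useful gait parameters — step time, cycle (stride)
time, ambulation time, cadence, velocity, step length — are all
functions of the *timestamps* of initial contacts, so the whole task
reduces to finding peaks in time, never calibrated amplitudes. That is
what makes the approach robust: the pipeline is, by construction,
invariant to positive rescaling of the raw traces, and every test of
this package asserts that invariance bit-exactly.

## The detection model, stage by stage

**Normalization.** Each trace is min-max scaled to [0, 1] and then
mean-centred. Scaling precedes centring so that the percentile-based
peak threshold later on refers to a common amplitude scale across
sensors with different gains.

**Rolling-maximum aggregation.** The composite signal takes, at each
grid time, the maximum over all sensors and over a window of
`agg_window_s` seconds. Two jobs at once: the sensor nearest the
current footstep dominates (counteracting distance damping), and the
window rectifies the oscillatory burst into its upper envelope. The
second job fixes the window's scale: it must span at least one period
of the burst's dominant frequency, or the envelope collapses between
crests. The default is 0.08 s; with ~22 Hz bursts (45 ms period) a
0.05 s window at 100 Hz spans only 40 ms and demonstrably degrades
recovery, which is why the slightly wider default was chosen.

**Compound top-hat filter.** Grayscale erosion and dilation with a
spherical structuring element (SE) of radius 0.2 s — the duration of
an average single footstep — yield opening (spike removal) and closing
(dip filling). Their average tracks the local baseline; subtracting it,

$$\mathrm{CTF}(x) = x - \tfrac12\,(\gamma_g(x) + \varphi_g(x)),$$

removes low-frequency noise while preserving any transient narrower
than the SE. Compared with a bandpass filter there is no frequency
mixing issue when noise and signal overlap spectrally, and compared
with a one-sided (white or black) top-hat both polarities of baseline
excursion are attenuated.

The SE's vertical scale is genuinely underdetermined: the radius is a
time, but grayscale morphology needs heights in amplitude units. The
package defaults to a spherical profile with peak height 1.0 on the
normalized scale and exposes both the height and a flat SE as options.
We evaluated heights 0.3, 0.5, 1.0 and flat on 1000 simulated walks;
recovery was statistically indistinguishable for 0.5 and 1.0 and
clearly worse for 0.3 and flat, so the unit default stands.

**Smoothing.** A Hamming window and a rectangular window, each of
0.1 s radius (21 taps at 100 Hz), unit DC gain, reflect padding. The
Hamming filter boosts genuine peaks relative to sample-scale jitter;
the rectangular filter merges closely adjoining double peaks (e.g. the
two lobes of one burst) into a single maximum.

**Peak detection.** The filtered signal is re-min-max-normalized
(the threshold rule is defined on normalized amplitudes, so the
renormalization is on by default and configurable). Local maxima are
found with plateaus resolved to their midpoint sample (lower middle on
even plateaus — a convention, asserted in tests). Candidates must
reach the 95th percentile of the signal's amplitude distribution, and
survivors are greedily pruned highest-first (earlier peak on ties)
until no two are closer than 50 ms.

One property of the percentile rule deserves emphasis, because it only
became visible through simulation: **the threshold presumes footstep
transients are temporally sparse in the recording.** The 95th
percentile of *all* samples sits below the weakest footstep peak only
when peak lobes occupy a few percent of the trace. Recordings that
bracket the walk with quiet periods (as real session recordings do)
satisfy this; a trace cropped tightly to the walk, or conversely a
short walk inside a very long quiet recording, moves the threshold
into the peak-lobe or noise-bump distribution respectively and costs
steps at either end. The simulator's default 12 s lead-in/lead-out
keeps occupancy balanced across 6–12-step walks.

## Gait arithmetic

With contacts $t_1 < \dots < t_n$ and intervals $d_i$: step time
$= \overline{d_i}$, cycle time $= \overline{t_{i+2} - t_i}$, ambulation
time $= \sum d_i = t_n - t_1$, cadence $= 60 n / \text{ambulation}$,
velocity $=$ walkway length / ambulation time, step length $=$
velocity $\times$ step time. Cadence deliberately uses the raw count
$n$ (the stated ratio of identified steps to ambulation time), not the
more common $n - 1$ interval count. The temporal parameters are exact
functions of the timestamps; velocity and step length are
approximations that assume the walk spans the active walkway length
(488 cm by default) — at 100 Hz the sampling rate is too low for
time-difference-of-arrival localization of individual steps, so no
per-step spatial estimate is attempted. With exactly two events, cycle
time and step length are reported as `NA` rather than guessed. Foot
labels alternate from an externally supplied first foot and are purely
presentational. A TUG (timed up-and-go) pass is timed from the first
to the last detected peak.

## The synthetic-data generator

Real recordings of this kind are generally not shareable, so the
package treats the simulator as a first-class, tested module; all
quantitative claims about the pipeline are claims about this generator.

Each walk draws inter-step intervals from a truncated normal
(mean 0.604 s, SD 0.03 s within a walk, cut at ±3 SD), places contacts
at uniform spatial increments half a stride inside the 4.88 m active
area (a walker stands at the walkway end, so first/last contacts land
inside it), and synthesizes each sensor's trace as a sum of Gabor
wavelets — Gaussian-windowed cosines, the standard synthetic seismic
impulse — centred at the step time plus a propagation delay
$d/c$ ($c = 500$ m/s), with amplitude $1 - 0.08\,d$ per metre of
sensor distance, plus white noise (SD 0.04) and sub-2 Hz drift (a
0.5 Hz sinusoid plus a random-walk component, amplitude 0.08) that
exercises the CTF's baseline attenuation. Three sensors sit 1.5 m
apart on alternating sides of the walkway. Each walk carries a random
sub-sample start phase: a simulated first contact aligned exactly with
the sampling grid would be the one event with zero quantization error
and would bias interval estimates detectably at sub-millisecond
scales.

Parameter choices worth recording:

* **Wavelet centre frequency 22 Hz.** Footstep bursts are broadband
  above the geophone's 4.5 Hz natural frequency; at 100 Hz sampling a
  15 Hz carrier puts the first crest 1.5 samples after onset and a
  25 Hz carrier is stroboscopically degenerate ($f_s/f_0 = 4$ exactly,
  so crest capture varies between 0.71 and 1.0 per step). 22 Hz is
  realistic and incommensurate with the grid.
* **Symmetric wavelet, centred at the step time.** A causal decaying
  sinusoid starting at the contact would shift every detected peak
  late by roughly the smoothing centroid of its envelope (~35 ms
  measured) — an artifact of the waveform, not the detector. With the
  wavelet centre as the ground-truth fiducial, the noiseless trace
  argmax coincides with the step time to within one sample.
* **Attenuation 0.08/m.** Single-sensor recovery on real floors is
  known to be near-complete at up to ~4 m; stronger attenuation
  regimes contradict that observation.
* **Cohort distribution.** Between-walk mean step intervals are drawn
  with SD 0.092 s, truncated at ±2 SD: the cohorts this emulates are
  healthy adults walking, with cadence spanning roughly 101 ± 28
  steps/min; untruncated tails produce near-running gaits outside the
  method's design envelope (and outside any walking cohort's observed
  support).

**What the simulator does not emulate:** dispersive or multipath wave
propagation in real floor slabs, per-step amplitude variability,
footwear and surface effects, multiple simultaneous walkers, sensor
clock skew, or real geophone noise spectra. Passing the synthetic
suite therefore demonstrates the pipeline's correctness and its noise/
drift robustness in this model, not performance on any particular
building or cohort.

## Numerical choices and degenerate inputs

* Morphology uses a shrinking-window boundary (min/max over the
  in-bounds SE support, no padding), so no fabricated extremes appear
  where the first and last steps live. With this policy erosion and
  dilation remain adjoint, hence opening/closing are idempotent,
  anti-extensive/extensive — properties the test suite asserts
  bit-exactly for flat SEs and to 1e-12 for spherical ones (heights
  are irrational, so float associativity costs an ulp).
* Equivalence with brute-force double-loop oracles is asserted exactly
  on random signals for all five operators.
* Smoothing kernels are unit-sum with reflect padding: constants pass
  through unchanged (DC gain exactly 1).
* Constant or empty signals yield zero events with a warning rather
  than an error; a constant trace min-max-normalizes to zeros with a
  warning; fewer than two events refuse gait arithmetic.
* The greedy minimum-distance pruning resolves ties by keeping the
  earlier peak; plateau maxima use the lower-middle sample.
* CSV round trips: traces are written with 17 significant digits
  (bit-exact round trip), reports with 15 (human-readable, round trips
  far below the 1e-9 contract).

## Known limitations

* **Timestamp resolution is interference-limited, not just
  grid-limited.** After ±0.2 s of smoothing, peak lobes are so flat on
  top that the argmax sample is pinned by neighbouring-step
  interference; per-step timing errors of a few milliseconds are
  deterministic given the interval pattern, and the first/last steps
  of a train carry a slightly different expected lag than interior
  ones (the baseline under them is one-sidedly elevated by the
  morphological closing bridging adjacent steps). Interval-based
  parameters inherit only the edge difference, a sub-millisecond
  effect.
* **Fast, dense walks are the hard case.** At step intervals below
  ~0.5 s the closing bridges adjacent bursts and the percentile
  threshold rises into the peak lobes; about 0.5% of simulated walks
  under default conditions lose one edge step. This mirrors the
  method's stated design point: the SE radius encodes an average
  footstep duration, not a running gait.
* Statistical agreement at near-perfect recovery needs care: with
  sub-millisecond jitter a paired t-test can flag a 0.3 ms bias as
  significant; Bland-Altman limits and regression slopes are the
  interpretable quantities at that scale.

## Problem sizes used by the test suite

The bundled checks simulate cohorts of 50–100 walks of 6–12 steps
(roughly 25–40 s of 3-sensor signal per walk at 100 Hz), which keeps
the full suite and the acceptance script within a few minutes on one
CPU while estimating recovery rates at the percent level; the same
generators scale to larger cohorts by changing `n_walks` and the
scenario fields.
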