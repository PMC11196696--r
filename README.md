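# seismogait

Quantifying human gait from floor vibrations. Footsteps excite a floor
like miniature earthquakes; geophone-based seismographs placed along a
walkway record those transients at ~100 Hz. **seismogait** turns such
recordings into the spatiotemporal gait parameters used in clinics
(step time, cycle time, ambulation time, cadence, velocity, step
length) and into timed up-and-go (TUG) test timings — without cameras,
body-worn sensors, or pressure-sensitive walkways. It is aimed at
researchers in digital gait analysis and ambient health monitoring who
want an unobtrusive, amplitude-robust step detector plus the
method-agreement statistics needed to validate it against a reference
system.

## Method

The step-extraction pipeline works on min-max normalized, mean-centred
traces x_s(t) from S sensors:

1. **Aggregation.** The sensors are combined by a rolling maximum,

       m(t) = max_{s, |u - t| <= w/2} x_s(u),

   which counteracts per-sensor damping (the nearest sensor dominates)
   and, with `w` spanning one period of the transient's dominant
   frequency, forms the upper envelope of the oscillatory bursts.

2. **Compound top-hat filter (CTF).** With grayscale erosion
   `(x ⊖ g)(t) = min_k [x(t+k) − g(k)]` and dilation
   `(x ⊕ g)(t) = max_k [x(t−k) + g(k)]` for a spherical structuring
   element g of radius 0.2 s (the duration of an average footstep),
   opening `γ(x) = (x ⊖ g) ⊕ g` and closing `φ(x) = (x ⊕ g) ⊖ g`, the
   noise-attenuated signal is

       CTF(x) = x − (γ(x) + φ(x)) / 2.

   The opening/closing average tracks the slowly varying baseline
   (building sway, drift) while ignoring transients narrower than the
   SE, so the subtraction removes low-frequency noise without the
   frequency-mixing problems of bandpass filtering.

3. **Smoothing and peak detection.** A unit-sum Hamming filter and a
   rectangular (moving-average) filter, both of 0.1 s radius, boost
   genuine peaks and merge closely adjoining double peaks. Footstep
   events are the local maxima of the re-normalized signal that reach
   the 95th percentile of its amplitudes, greedily pruned to a minimum
   inter-peak distance of 50 ms. Only the peak *timestamps* leave this
   stage — the pipeline is invariant to positive rescaling of the
   input.

4. **Gait arithmetic.** For ordered initial contacts t_1 < … < t_n with
   intervals d_i = t_{i+1} − t_i:
   step time = mean(d_i); cycle time = mean(t_{i+2} − t_i);
   ambulation time = Σ d_i; cadence = 60·n / ambulation time;
   velocity = walkway length / ambulation time;
   step length = velocity · step time. A TUG pass is timed from the
   first to the last detected peak.

The package also ships a multi-sensor walk simulator with known ground
truth (three sensors 1.5 m apart on alternating sides of a 4.88 m
walkway, Gabor-wavelet footstep bursts with distance attenuation and
propagation delay, white noise plus sub-2 Hz drift) and the agreement
battery used to compare two measurement systems: paired t-tests with
Cohen's d, simple linear regression with an F-test, Pearson r with
Fisher confidence intervals, and Bland-Altman limits of agreement.

## Worked example

```r
library(seismogait)

sim <- simulate_walk(walk_scenario(n_steps = 8, seed = 42))
events <- extract_footsteps(sim$traces)
round(events$times, 2)
#> [1] 12.02 12.65 13.25 13.86 14.48 15.09 15.69 16.34
round(sim$truth$step_times, 2)
#> [1] 12.00 12.65 13.24 13.85 14.47 15.09 15.69 16.34

compute_gait_parameters(events, 488)
#> <gait_parameters>
#>   step time           0.617 s
#>   cycle time          1.227 s
#>   ambulation time     4.320 s
#>   cadence            111.11 steps/min
#>   velocity           112.96 cm/s
#>   step length         69.71 cm
#>   steps                   8
```

All eight simulated footsteps are recovered within one or two samples
(10–20 ms) of the ground truth. The gait parameters follow: an average
step every 0.617 s, a stride (cycle) of about twice that, a 4.32 s
pass over the 4.88 m walkway, hence 113 cm/s walking speed and a
69.7 cm average step.

A synthetic validation study — the analogue of comparing the
seismograph system against a reference system over a cohort of walks —
takes one call:

```r
study <- run_validation_study(n_walks = 50, seed = 1)
study$reports$step_time
#> <agreement_report> step_time (n = 50 walks)
#>   means            0.6119 vs 0.6109 (SD 0.0766 / 0.0777)
#>   paired t(49)     t = 0.988, p = 0.328, d = 0.140
#>   regression       slope 0.982, R^2 = 0.991, F = 5362.7
#>   Pearson r        0.996 [0.992, 0.997]
#>   Bland-Altman     bias 0.0010, LoA [-0.0134, 0.0154]
```

Step time recovered across 50 walks agrees with ground truth with a
1 ms bias, R² of 0.99, and no significant paired difference —
the qualitative surface reported for seismograph-vs-walkway
comparisons on real cohorts.

The same operations are scriptable from a shell via
`inst/cli/seismogait.R` (subcommands `simulate`, `detect`, `analyze`,
`tug`, `compare`, `study`).

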