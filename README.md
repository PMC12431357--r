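# uwbvitals

Non-contact vital-sign extraction from impulse-radio ultra-wideband
(IR-UWB) bio-radar mounted on a moving platform, such as a hovering
drone searching for survivors. The package recovers respiration rate
(RR) and heart rate (HR) from the slow-time × fast-time echo matrix of
a radar observing a person, in the presence of two interferences that
dominate airborne operation: platform motion and vegetation clutter.

## The method

A chest wall at range $d(t)$ modulates the echo phase by
$\theta(t) = 4\pi d(t)/\lambda$, with

$$d(t) = d_0 + A_r\sin(2\pi f_r t) + A_h\sin(2\pi f_h t) + d_p(t)$$

($A_r, f_r$ respiration, $A_h, f_h$ heartbeat, $d_p$ platform motion).
Processing follows the chain:

1. **Range-migration compensation** — integer-bin envelope alignment by
   cross-correlation, then fine per-frame phase compensation against a
   benchmark built from prominent static scatterers;
2. **Clutter removal** — 100-frame moving-average DC/drift canceller
   per range bin;
3. **Target localization** — maximum slow-time energy over bins;
4. **Respiration** — the five slow-time phase channels around the
   target bin, baseline-removed, separated by JADE (whitening with
   noise-variance correction, fourth-order cumulant matrices, joint
   approximate diagonalization). Fourth-order cumulants of Gaussian
   processes vanish, so Gaussian grass clutter is suppressed by
   construction; the respiratory component is the one concentrating
   its spectral power in 0.1–0.6 Hz;
5. **Heartbeat** — band-pass 0.85–3.3 Hz of the target-bin signal,
   feedback-notch cascade $(1+\alpha)G(z)/(1+\alpha G(z))$ removing the
   3rd–5th respiratory harmonics, spectral peak search in 0.85–2 Hz.

A physics-based simulator (`simulate_cube()`) generates radar cubes
with known ground truth — sinusoidal chest displacement, platform
motion, static reflectors, band-limited Gaussian clutter — so the whole
pipeline is testable without hardware. Evaluation utilities implement
the spectral peak-to-background SNR, the rate-accuracy metric
$(1-|f_{est}-f_{ref}|/f_{ref})\cdot 100$, and Anderson–Darling /
Gaussian-fit clutter characterization.

## Worked example

A 30 s simulated hover at 17 Hz frame rate: breathing target at 2 m
(RR 0.3113 Hz, HR 1.25 Hz), sinusoidal platform drift of 0.15 m at
0.1 Hz (a three-bin range migration), four static background
reflectors, Gaussian clutter at one fifth of the echo amplitude.

```r
library(uwbvitals)
report <- run_pipeline(list(
  simulate = list(
    d0 = 2.0, fr = 0.3113, fh = 1.25,
    platform_motion = list(model = "sinusoid", amplitude = 0.15, frequency = 0.1),
    reflectors = list(list(range = 1.2, amplitude = 0.8),
                      list(range = 3.5, amplitude = 1.2),
                      list(range = 4.5, amplitude = 0.9),
                      list(range = 5.3, amplitude = 0.7)),
    clutter = list(model = "gaussian", sigma = 0.2),
    noise_std = 0.02),
  metrics = list(rr_reference = 0.3113, hr_reference = 1.25),
  seed = 1))
report
#> <vitals_report>
#>   RR 0.3104 Hz (18.6 breaths/min), accuracy 99.71%
#>   HR 1.2556 Hz (75.3 beats/min), accuracy 99.55%
#>   SNR: respiration 17.71 dB, heartbeat 14.22 dB
#>   target bin 40, respiratory component 1, notches at 0.931, 1.242, 1.552 Hz
```

The report reads: the target was localized at range bin 40 (2.0 m at
0.0514 m/bin); JADE's first component was selected as respiration and
its spectral peak gives RR = 0.3104 Hz, 0.0009 Hz from the configured
truth; the 3rd–5th harmonics of that fundamental were notched (note the
4th at 1.242 Hz sits 8 mHz from the true heart line — the notch is
narrow enough to spare it) and the remaining spectral peak gives
HR = 1.2556 Hz. Accuracies are computed against the supplied reference
rates; SNRs are the in-band spectral peak over the mean residual.

A YAML-driven command-line front end is installed under
`inst/cli/vitals.R` (`run`, `simulate`, `accuracy` subcommands), and
`run_pipeline()` writes every intermediate artifact (aligned cube,
components, waveforms, report JSON, stage log) when given an
`out_dir`, so each stage can be re-run in isolation.

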