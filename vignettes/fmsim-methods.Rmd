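---
title: "Models and methods behind fmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmsim)
```

`fmsim` is a software twin of a laboratory fetal-movement simulator: a
prestressed silicone membrane standing in for a gravid abdomen, kicked by
linear actuators, instrumented with candidate vibration sensors. This
vignette records the models the package implements, the assumptions and
calibrations behind them, and the choices made where the design was
genuinely open.

## 1. Membrane mechanics

The gravid abdomen is idealized as a **single-layer clamped membrane**. The
layered anatomy (fetal membrane, uterine wall, abdominal wall) is collapsed
into one material by thickness-weighted averaging of Young's modulus and
Poisson's ratio, a thickness-weighted density over the uterine and
abdominal walls only (no density is reported for the fetal membrane), and a
total thickness equal to the sum of layers (`composite_properties()`).

Two caveats are built into the packaged configuration:

* The published weighted-average row for the 30-week abdomen
  (E = 151.37 kPa, μ = 0.48, ρ = 982.86 kg/m³, h = 38.49 mm) is **not**
  exactly reproducible by direct thickness weighting of the published layer
  values (which gives E ≈ 157 kPa). The published row is shipped as the
  canonical curved-abdomen material (`abdomen_reference()`) and used for all
  downstream design numbers; `composite_properties()` remains available for
  user-supplied layer tables.
* A Poisson ratio of 0.5 (incompressible abdominal wall) is accepted as an
  aggregation input, but the composite ratio is clamped strictly below 0.5
  so the flexural rigidity D = Eh³/12(1−μ²) stays finite.

**Curved design model.** The first-mode natural frequency of the doubly
curved clamped membrane uses the Rayleigh closed form implemented in
`natural_frequency_curved()`. The bracket of that formula was verified
numerically before being frozen: with the canonical material, equal radii
of 118.1 mm and sides equal to the semicircumference, it yields 33.445 Hz,
within 0.05% of the 33.46 Hz design value; in the flat limit (radii
→ 10⁶ m) it agrees with the flat-membrane formula to within 1% (Rayleigh
constant 72·18 = 1296 vs Galerkin 36.11² ≈ 1303.9), which the test suite
checks.

**Flat testbed.** The silicone testbed obeys the Galerkin solution
(`natural_frequency_flat()`, `damped_natural_frequency()`) with the
first-mode square-membrane constant Λ = 36.11², the only mode supported;
rectangular constants and higher modes are out of scope. The damping ratio
`damping_ratio()` is implemented **with an explicit square root**,
ζ = √(1 − (f_nd/f_n)²): only this form is a fraction of critical damping,
and only it reproduces ζ = 0.80 from the characterized frequencies
(f_n = 31.24 Hz undamped, f_nd = 18.70 Hz measured).

**Prestress.** Uterine wall tension is emulated by stretching the clamped
membrane; `prestress_elongation()` implements δ = aσ(1−μ)/E from
plane-stress Hooke's law under equal biaxial tension. The packaged tension
table covers 20/25/30 gestational weeks (11.9/16.3/22.8 kPa mean). Only the
mean tensions are used: the reported 25-week elongation *range* duplicates
the 20-week range and is treated as unreliable. `testbed_membrane()` rounds
the applied elongation to whole millimetres because that is how the
stretching mechanism applies it; with the 30-week tension this gives
11 mm on the 167 mm membrane (side 178 mm) and an undamped frequency of
31.24 Hz. Using the unrounded elongation would give 31.35 Hz.

The design inversion `side_length_for_frequency()` returns ≈ 172 mm for
the curved-model frequency; the rig's published sizing step gives 171 mm.
The ~0.6% gap is consistent with intermediate rounding in that step
(whether it used the as-built 39 mm thickness or a nominal one is not
recorded); the package tolerates it and documents it rather than matching
the printed value by construction.

## 2. The kick synthesizer

### Drive

A kick is the **trapezoidal** trajectory of the actuator tip: rise at the
actuator speed (12.43 mm/s no-load maximum) to the wall displacement, an
optional pause, and a linear return; total duration 2d/v + pause.
Displacements below 0.5 mm are rejected — the actuators' 0.4 mm
repeatability makes smaller kicks unreliable. Measured kick durations on
the rig slightly exceed 2d/v (1.63 s vs 1.61 s at 10 mm with the
cylindrical probe; a few percent more with the heavier hemispherical
probe), attributable to loaded-actuator slowdown; a `speed_derating`
factor is exposed for users who want to emulate it, and defaults to 1
(no-load speed). Kick reaction forces are piecewise-linear interpolations
of the rig's per-probe calibration knots (10/15 mm), linearly extrapolated
and floored at zero.

### Membrane response model

`membrane_response_model()` is **phenomenological plumbing, calibrated, not
derived**: the physical rig provides observations (spectra, thresholds,
trends), not transfer functions. The surface displacement at distance r
from the impact point is the sum of three parts, all attenuated by
exp(−r/L):

1. **Forced component** — the drive convolved with a raised-cosine kernel
   of width 0.40 s (finite contact area and membrane compliance; it also
   keeps the drive's corner singularities out of the acceleration channel),
   scaled by a coupling gain (default 1).
2. **Free ringing** — a damped sinusoid at the membrane's damped natural
   frequency f_nd = 18.70 Hz, launched at each velocity discontinuity of
   the trapezoid, amplitude proportional to the velocity step and to
   (d/10 mm)²; injected through the closed-form displacement, velocity and
   acceleration of the decay so that onsets create no numerical
   differentiation spikes.
3. **Slow sway** — a damped 2.25 Hz oscillation of the tensioned membrane
   excited when loading and unloading complete, amplitude ∝ (d/10 mm)² ·
   3 mm. It supplies the displacement-proportional low-frequency content
   observed on the rig (acoustic/piezoelectric power concentrated around
   2 Hz) which a linear trapezoid response cannot: for large kicks the
   trapezoid fundamental (0.44 Hz at 14 mm) falls below the 1 Hz analysis
   corner and would otherwise vanish from the conditioned signal.

The attenuation length L = 0.202 m makes the signal *energy* halve over
about 7 cm, matching the monotone decay observed across 0–15 cm; no
attenuation law is available from the rig, so an exponential was chosen as
the simplest monotone form.

**Why two time constants.** The single-mode viscous model gives a decay
constant τ = 2ρh/k = 6.4 ms from the measured f_nd — that number is
computed (and tested) in the mechanics module. But the *observed* free
vibration cannot decay that fast: the measured frequency is repeatable to
±0.1 Hz across trials, and the ~19 Hz ridge is visible in spectrograms for
on the order of a second after the kick, both of which require a decay time
of hundreds of milliseconds (a 6.4 ms burst has a Lorentzian half-width of
~25 Hz and no localizable spectral peak — a time–bandwidth constraint, not
an implementation detail). The discrepancy means the f_n → f_nd drop is not
purely viscous (mass loading, air coupling and imperfect clamping also
lower the frequency). The synthesizer therefore carries its own ring
envelope constant, `ring_decay` = 0.30 s, calibrated to the observed
persistence and repeatability and consistent with complete decay well
before the 6 s noise-window offset, while `time_constant()` continues to
report the viscous estimate.

**Why the ring amplitude scales with displacement.** For a trapezoid the
velocity steps are ±v regardless of displacement, so a strictly
step-proportional ring would make the accelerometer's response independent
of kick intensity — and a detection threshold in displacement would not
exist at all. Deeper indentation engages a larger contact area and couples
the release more strongly into the fundamental mode; this is modelled as
the (d/d_ref)² factor. The quadratic exponent gives a 2.25× amplitude
separation between 1.0 and 1.5 mm kicks, a comfortable margin against
noise in the threshold study.

### Sensor models

Sensor transfer behaviours are qualitative emulations of the tested
hardware, frozen in `inst/extdata/sensors.yaml`:

| sensor | responds to | band shaping | sensitivity | noise RMS |
|---|---|---|---|---|
| acoustic | surface displacement | flat 1–100 Hz | 100 V/m | 2.0 mV |
| piezoelectric | displacement rate | 4th-order low-pass, 10 Hz | 50 V/(m/s) | 5.0 mV |
| accelerometer | acceleration (3 axes) | 1st-order RC, 50 Hz | 0.0306 V/(m/s²) (300 mV/g) | 1.55 mV/axis |

The accelerometer emits three axis channels with the vibration projected on
the z axis plus the 1 g static offset, and independent noise per axis; the
projection choice is immaterial to the Euclidean magnitude the pipeline
uses. The **noise floors are free calibration parameters, tuned once** so
that the detection-threshold study reproduces the observed input
thresholds (0.5 mm acoustic, 0.5 mm piezoelectric, 1.5 mm accelerometer at
20 cm with the cylindrical probe), and then frozen; they are calibrated,
not measured. The same applies to the ring and sway amplitudes.

### What the generator emulates — and what it does not

The synthesizer reproduces: trapezoidal kick kinematics and durations;
exponential spatial attenuation; a persistent ~19 Hz free vibration and a
~2 Hz sway; the qualitative frequency separation between the three
sensors; displacement- and distance-dependent signal energy trends; and
per-sensor detection thresholds. It does **not** model: multi-mode or
finite-element membrane dynamics; probe contact mechanics beyond the force
interpolation; actuator load–speed curves; maternal-movement or ambient
artefacts; sensor nonlinearity or drift. Passing tests on synthetic data
therefore demonstrate the internal consistency of the pipeline and the
calibrated emulation — not validation against new hardware or clinical
recordings.

## 3. The characterization pipeline

All sensor series are conditioned with a **4th-order zero-phase Butterworth
band-pass, 1–40 Hz** (the expected vibration band). Zero-phase filtering is
forward–backward with odd (reflective) end padding of two periods of the
low corner; the series mean is removed first, since a static offset (the
accelerometer's 1 g) otherwise excites a slow edge transient through the
1 Hz corner. The accelerometer magnitude (Euclidean norm of the three
axes) is computed on the **raw** axes, before filtering: with the 1 g
offset present the norm is locally linear in the vibration signal, whereas
norm-after-filtering would full-wave-rectify the ringing and double its
apparent frequency.

The noise estimate e is the mean |V| over a 2 s quiet window; the
automated choice places it 6 s after the previous kick (or in the pre-kick
lead-in for the first kick) so the free vibration has fully decayed. An
explicit `quiet_start` is also accepted. The threshold is h = 5e — the
multiplier 5 was found by trial and error on the rig to give the most
suitable threshold and is the package default. A sample exactly at the
threshold counts as noise (the signal condition is strictly |V| > h).
Signal and noise energies, counts and the SNR follow; when the mean signal
power does not exceed the noise power the SNR is undefined and reported as
a typed condition (or `NA`), never a numeric sentinel.

Spectral estimates use Hann windows: Welch PSDs with 1 s windows and 50%
overlap (1 Hz resolution), spectrograms with 0.5 s windows and 80% overlap
(2 Hz bins, 100 ms hop). The Welch estimator is implemented in the package
(averaged modified periodograms, one-sided density scaled so the integral
matches the variance); no installed package provides one, and the
spectrogram shares its windowing. The **dominant frequency mode** is the
arg-max of the PSD within the 1–40 Hz analysis band, ties broken toward the
lower frequency (the convention is unspecified upstream; the tie rule is
frozen and tested).

## 4. Experiments

The three case-study designs are reproduced end-to-end on synthetic data:

* `run_displacement_sweep()` — 2–14 mm in 2 mm steps, hemispherical probe,
  sensors at 5 cm, 10 repetitions per condition, mean ± SD of SNR, signal
  energy and dominant mode.
* `run_distance_sweep()` — 0–15 cm in 3 cm steps at 10 mm displacement.
* `run_threshold_study()` — cylindrical probe at 20 cm, displacement
  rising from 0.5 mm in 0.5 mm steps until each sensor detects.
* `run_comparative_response()` — 14 mm kicks at 5 cm; responses,
  spectrograms, repetition-averaged PSDs.

Impact point and sensor are placed symmetrically about the membrane centre
along a diagonal, as on the rig (20 cm separation does not fit the 178 mm
membrane any other way). Per-repetition seeds derive from the master seed
by the fixed rule `master·10007 + condition·211 + repetition` (mod 2³¹−1),
so each kick is independently reproducible. Every saved experiment carries
a provenance log (kind, sweep, seeds, package version, timestamp).

**Detection rule.** On the physical rig, "recognizing a kick" was a visual
judgment of the sensor trace. The package operationalizes it as: at least one contiguous run of
supra-threshold samples (|V| > 5e) lasting ≥ 10 ms inside the kick
interval (kick start to return end plus a free-vibration allowance). The
run requirement makes the rule robust to isolated noise exceedances while
remaining satisfiable by the oscillatory ring (whose half-period at
18.7 Hz is 27 ms).

## 5. Numerical choices and degenerate inputs

* Strict SI internally (m, Pa, kg/m³, s); packaged YAML configs declare
  mm/kPa and are converted at the boundary.
* Coincident trapezoid events (zero pause) merge into a single −2v
  velocity step before ring injection.
* `damped_natural_frequency()` raises a distinct "overdamped" error when
  the radicand is non-positive; `snr_db()` raises a typed
  `fmsim_snr_undefined` condition; empty sample sets have zero energy.
* Welch/spectrogram require at least one full window and error otherwise.
* Synthesis restores the caller's RNG state; identical inputs and seed give
  bit-identical recordings.

Test-suite problem sizes: single-kick recordings of 8–12 s at 2 kHz
(16k–24k samples), sweeps of 6–7 conditions × 10 repetitions, ten-seed
recovery checks; the full suite runs in well under a minute.

## 6. Known limitations

* All response components share one spatial attenuation law; real membrane
  responses are direction- and boundary-dependent.
* The ring and sway displacement-coupling exponents are calibration
  constants with a plausibility argument, not measurements; transferring
  the calibration to a different membrane or probe requires re-tuning
  against that rig.
* The acoustic sensor's dominant mode stays near 2 Hz across the
  displacement sweep, whereas the rig showed a transition from ~19 Hz at
  small displacements; reproducing that transition would need a
  displacement-dependent balance between sway and ring that the present
  calibration does not attempt.
* Only the first vibration mode of a square membrane is modelled; kick
  angle is recorded in profiles but does not alter the response model.
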