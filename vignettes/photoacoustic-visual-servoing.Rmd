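---
title: "Photoacoustic visual servoing of a needle tip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoacoustic visual servoing of a needle tip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interventional procedures need continuous visualization of a tool tip —
a biopsy needle, a catheter, a guide wire — in media where conventional
ultrasound often fails: through bone, or through the multiple scattering
near-field layers of overweight patients, where acoustic clutter can hide
the tool entirely. Photoacoustic imaging sidesteps much of this: an
optical fiber threaded through the needle delivers a laser pulse at the
tip, the absorbed light launches an acoustic wave from a point-like
source, and a linear ultrasound array receives it after **one-way**
propagation. A robot holding the probe can then close the loop: segment
the bright tip signal in every frame, translate the probe so the signal
sits at the lateral image center, and scan in elevation if the tip is
lost out of plane.

`pavservo` implements this entire pipeline desk-scale: a seeded synthetic
channel-data generator standing in for the laser/tissue/scanner chain,
delay-and-sum (DAS) beamforming with envelope detection, the
segmentation-plus-consensus tip tracker, the centering/search controller,
and harnesses for the tracking, centering, angled-insertion,
perturbation-recovery and fluence-sweep studies.

## The synthetic acquisition model

One laser shot produces a `channel_frame`: an `n_samples x n_elements`
matrix of receive traces. For a fiber tip at probe-frame position
$(x_s, y_s, z_s)$ and element lateral positions $x_i$, each element
receives a Gaussian-modulated sinusoid at the array center frequency
$f_0$ delayed by the one-way time of flight
$\tau_i = r_i / c$, $r_i = \sqrt{(x_i - x_s)^2 + y_s^2 + z_s^2}$, with
amplitude

$$A_i \;=\; \Phi \cdot s_m \cdot \frac{r_0}{r_i} \cdot
  10^{-\alpha f_0 r_i / 20} \cdot w(y_s),$$

where $\Phi$ is the fluence at the fiber tip
(`energy_to_fluence(E, d)` $= E / \pi (d/2)^2$ with the core diameter in
cm; 1.58 mJ through a 1 mm core gives 201.2 mJ/cm²), $s_m$ a
tissue-dependent source-strength multiplier, $r_0 = 10$ mm a reference
range for the $1/r$ spherical spreading, $\alpha$ the amplitude
attenuation in dB/cm/MHz applied once at the propagation distance (no
dispersion — amplitude and SNR trends are the goal, not waveform
fidelity), and $w$ the Gaussian elevation sensitivity with full width at
half maximum `elevation_beamwidth` (default 3 mm). The elevation profile
is the only out-of-plane physics modeled: a tip a few beamwidths out of
plane is simply invisible, which is the dichotomy the servo logic needs.

Two degradations are added. Electronic noise is white Gaussian with
per-preset `noise_sigma`. Acoustic clutter — in the physical experiments
a wire-mesh layer causing multipath scattering, for which no tractable
physical model exists — is surrogated by band-limited noise (Gaussian
spectrum around $f_0$) correlated across neighboring elements (Gaussian
kernel, 4-element correlation length; the correlation length is a free
parameter of the surrogate) and scaled to `clutter_level` times the
peak of the clean signal, so clutter tracks fluence the way scattered
signal energy does. The clutter term spans the whole receive window,
which is what degrades the pre-arrival noise gate and hence the measured
channel SNR, reproducing the observed monotone decrease with clutter.

All randomness in a frame flows from one explicit `seed`; identical
inputs and seed give bit-identical frames.

### The pulse model and the resolution calibration

The array defaults describe a 5.5 MHz linear probe with 61% fractional
bandwidth (−6 dB), 128 elements at 0.3 mm pitch (38.4 mm field of view)
sampled at 40 MHz. A Gaussian spectrum whose −6 dB full width equals
$0.61 f_0$ fixes the envelope time constant
$\sigma_t = 1 / (2\pi\sigma_f)$. The element bandwidth alone, however,
underpredicts the axial extent of the *system* point-spread function,
which in practice also carries the laser pulse width, the acoustic
source size and the receive electronics. We therefore include a single
calibration factor `psf_axial_scale` (default 3.5) multiplying
$\sigma_t$, chosen once so that a simulated 0.35 mm thread target
(modeled as a disc of sub-resolution point sources) images at
approximately 1 mm axial FWHM averaged over 10–30 mm depths. The
receive aperture is F-number limited with Hann apodization; the default
F-number 3.3 is likewise calibrated once so the same thread images at
approximately 2 mm lateral FWHM. `measure_system_resolution()`
regression-tests both numbers.

## Beamforming and image statistics

`das_beamform()` is receive-only DAS: each pixel sums, over the elements
inside its depth-proportional aperture, the channel samples delayed by
the one-way pixel-to-element flight time, with linear interpolation for
fractional delays and normalization by the apodization weights (so image
amplitude tracks channel amplitude, not element count). The compiled
kernel is checked against a naive triple-loop oracle to $10^{-9}$
relative. The default grid is conventional line-per-element imaging: one
lateral line per element and axial spacing $c/f_s$; the closed-loop
harnesses use `experiment_grid()` (5–35 mm window, axial spacing
$2c/f_s$), since centroid-based tip localization is insensitive to axial
sampling at that scale and the halved grid keeps the simulated studies
fast. Envelope detection is the magnitude of the FFT-based analytic
signal along depth; display images are log-compressed to 0 dB at the
frame maximum with a configurable dynamic range (30 dB for channel
quality displays, 60 dB for tissue overlays).

Image quality is quantified exactly as in the physical studies:

* contrast $= 20\log_{10}(S_i/S_o)$,
* SNR $= S_i/\sigma_o$,
* channel SNR $=$ RMS(signal gate) / RMS(noise gate) on the raw channel
  data.

$S_i, S_o$ are region means at the same depth inside/outside the tip
signal and $\sigma_o$ the background standard deviation. Two conventions
had to be fixed because they are underdetermined: all standard
deviations are **population** (divide by $N$) standard deviations, and
the channel-SNR gates are ±1 µs around the analytic arrival time at the
central 16 elements with a pre-arrival noise gate of equal size.
Because gate placement is a free choice, absolute channel-SNR values are
not comparable across implementations — only trends (clutter level,
energy) are.

## Tip segmentation and temporal consensus

Per frame, on the linear (pre-log) envelope:

1. **Dynamic threshold** at `threshold_fraction` (default 0.5) of the
   frame maximum. Half-maximum mirrors the FWHM convention used for
   resolution; thresholding the linear envelope rather than the
   log-compressed display keeps the rule scale-invariant.
2. **Opening** (erosion then dilation) with a radius-1 disk (3×3 cross),
   removing single-pixel regions; out-of-image neighbors count as
   background.
3. **Connected-component labeling**, 8-connectivity by default.
4. **Outlier-based label selection**: the largest-area label is the tip
   only if its area is a distinct outlier of the area histogram — above
   the upper Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$ (quartiles by linear
   interpolation of order statistics) — and at least `min_area` pixels.
   The fence needs at least four areas to mean anything: a lone label is
   accepted at `min_area`, and with two or three labels the largest is
   accepted when it is at least twice the runner-up. Ties for the
   largest area mean no distinct outlier. This step is what rejects
   reflection artifacts: they are dimmer and smaller than the true tip,
   so they either fall below the dynamic threshold or fail the outlier
   test.
5. **Centroid** (unweighted pixel mean) of the selected label, converted
   to mm via the grid.

`min_area = 20` px (on the experiment grid) was chosen from the observed
area statistics: tip blobs run ~70–180 px while thresholded noise
speckle that survives opening stays below ~20 px; the measured
false-positive rate on pure-noise frames is ≤ 5%.

Decisions are only reported after **spatiotemporal consensus**: the last
5 frames (including the current one — the buffer is the five most recent
results) must all contain a detection and all pairwise distances must be
within `consistency_radius` (default 2 mm, the lateral resolution); the
consensus location $\bar p$ is their arithmetic mean. Inside the servo
loop the consistency check runs in *world* coordinates (image position
plus probe position): the tip is stationary in the world while the probe
moves, so an image-frame check would spuriously fail during centering
motion.

## The servo state machine

While `TRACKING`, $\bar p$ is turned into the centering vector from the
center of the top image row; its lateral component is embedded as a
displacement along the image lateral axis and rotated through the
probe-to-end-effector calibration and the end-effector-to-base transform
($p_{robot} = R_{robot} R_{cal}\, (\bar p_{center,x}, 0, 0)^T$ —
translations do not apply to displacements). The motion command is
proportional with unit gain, clamped to 2 mm per step; controller
dynamics are deliberately not modeled. Only the lateral component drives
motion; the axial component is logged but unused.

Five consecutive consensus failures switch to `SEARCHING`: the probe
steps along a triangle wave on its elevation axis (out-of-plane loss is
what the angled studies produce; lateral loss is handled by centering
itself), spanning 60 mm total (±30 mm about the pose where the tip was
lost — the span is configurable since "a 60 mm scan" could also be read
as ±60 mm), 3 mm per step, starting toward positive elevation. A
detection during the scan holds the probe in place and must be confirmed
by the same 5-frame consensus before the mode returns to `TRACKING`; an
isolated false detection therefore resumes the scan instead of hijacking
the controller (without confirmation, noise-level false positives were
observed to drag the scan center tens of mm off the tip). Sixty fruitless
scan steps end in `TIMEOUT`, the single terminal state. The only legal
transitions are TRACKING→SEARCHING, SEARCHING→TRACKING and
SEARCHING→TIMEOUT, and the event log is checked against that set in the
test suite.

## The experiment harnesses and their study conditions

All harnesses are pure functions of (configuration, seed).

* **Tracking** (`run_tracking_experiment`): the probe is fixed, the
  needle advances 1.3 mm per step for 10 steps (13 mm total) at 20 mm
  depth; each position is segmented from a single acquisition and the
  per-step error is $|\,\lVert p_b - p_a\rVert - 1.3\,|$. Tissue
  deflection is modeled as an independent per-step Gaussian perturbation
  of the true tip position (lateral and axial) with preset-specific
  `deflection_sigma` — zero in water, smallest in muscle, largest
  through skull — the minimal stochastic surrogate that reproduces the
  observed tissue ordering of tracking error. Because consecutive
  positions carry independent deflections, the measured step picks up
  their difference; the test suite checks the resulting mean error
  against a Monte-Carlo oracle.
* **Centering** (`run_centering_experiment`): stationary tip, 10 trials
  with uniform random initial lateral offsets up to ±15 mm, 22 servo
  steps to quiescence, residual lateral offset $|d_p|$ read from the
  final frame. Non-convergence marks the trial failed rather than
  erroring. `anova_one_way()` compares $d_p$ across media.
* **Angled insertion** (`run_angled_experiment`): the needle advances
  13 mm along a line at {−20, −10, 0, +10, +20}° to the probe's lateral
  axis (elevation drift = advance × sin θ, up to 4.4 mm at ±20°,
  exceeding the 3 mm elevation beamwidth), spread over the first 40 of
  160 servo steps. With `perturb = TRUE`, one or two scripted 8 mm
  elevation displacements of the probe are injected mid-insertion.
  Success means the final mode is TRACKING with the tip detected —
  searches followed by recovery count as success, TIMEOUT as failure.
* **Fluence sweep** (`run_fluence_sweep`): energies 0.3–3.4 mJ
  (including 1.58 mJ), ten seeded acquisitions per condition, contrast /
  SNR / channel SNR averaged with population standard deviations, plus
  the fraction of acquisitions in which the tip was segmentable (at the
  lowest energies in noisy media the signal disappears under the
  electronic noise floor).

The preset tables (`tissue_preset`) carry the acoustic and behavioral
knobs: sound speed, amplitude scale, attenuation, noise floor, clutter
level, deflection scale. The per-tissue noise and deflection magnitudes
of the physical media are not quantified anywhere, so these are
calibration knobs of the generator, set once to plausible values
(channel SNR of order 10–100, water nearly noise-free, the clutter
preset identical to chicken thigh except `clutter_level = 0.5`) and
documented as such; they are not fitted to any reported number.

## What the generator does and does not emulate

It emulates: band-limited point-source wavefronts with correct per
element one-way delays, spherical spreading, bulk attenuation, elevation
roll-off, electronic noise, fluence-proportional signal and clutter, and
the closed-loop geometry of probe motion. It does **not** emulate: full
wave propagation (no speckle from distributed scatterers, no skull
aberration, no reverberation structure), optical fluence transport in
tissue, needle shaft signals, blood signals, or robot dynamics. Passing
the simulated studies therefore demonstrates the correctness and
robustness of the *algorithmic chain* under controlled degradations; it
does not certify performance in real tissue, where clutter is structured
rather than Gaussian and deflection is systematic rather than
independent per step.

## Numerical choices and degenerate inputs

Linear interpolation for fractional DAS delays; quartile type 7
(R's default linear interpolation of order statistics) for the Tukey
fence; population standard deviations throughout; FWHM by linear
interpolation of the half-maximum crossings of the profile through the
global peak (peaks on the image border are an error, as is a missing
crossing). All-zero images segment to "not found" rather than erroring;
all-zero envelopes cannot be log-compressed or thresholded (errors); a
source behind the array or deeper than the sampled window is a geometry
error, but a source merely out of plane yields a signal-free frame,
which is exactly what the search logic must cope with. Problem sizes in
the shipped tests and the acceptance script: 128-element frames of 1024
samples, 10 trials or seeds per condition, 100 noise frames for the
false-positive rate — the scales of the studies themselves; module tests
use a 32-element array with 512-sample frames.

## Known limitations

Absolute channel-SNR values depend on gate placement and are not
comparable across systems. The clutter surrogate's spatial-correlation
length is a free parameter. Amplitude saturation with fluence is not
modeled (signal is strictly linear in pulse energy). The controller has
no velocity limits, so "steps" are positions, not timed motion.
Elevation recovery relies on the tip re-entering the ±30 mm scan span;
drifts beyond it time out by design.
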