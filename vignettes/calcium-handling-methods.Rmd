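---
title: "Calcium-handling analysis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium-handling analysis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflux)
```

## The measurement and the model

caflux analyses recordings of cytosolic free Ca²⁺ in isolated ventricular
myocytes loaded with a dual-excitation ratiometric dye (FuraRed by
default), acquired under a concatenated protocol: a train of electrically
evoked Ca²⁺ transients (CaTs) at steady pacing, followed by rapid
application of caffeine, which locks the sarcoplasmic-reticulum (SR)
release channels open and dumps the SR content into the cytosol (the
caffeine transient, CaffT).

Two kinds of information are extracted:

* **Descriptive metrics** — diastolic, systolic and resting free
  \[Ca²⁺\], CaT amplitude, SR load (the CaffT amplitude), fractional
  release (CaT amplitude / CaffT amplitude), and the time to 90% CaT
  recovery (CaT₉₀).
* **Removal-flux decomposition** — during CaT recovery, cytosolic Ca²⁺ is
  removed by SERCA and NCX together; during CaffT recovery the SR cannot
  retain Ca²⁺, so removal is by NCX alone. Each removal pathway is
  summarised as a *rate constant* (s⁻¹): the slope of the relationship
  between removal flux and free \[Ca²⁺\] over the recovery phase. The
  flux is obtained from the recovery as
  \(J = -\beta\, dc/dt\), where \(\beta\) is the (constant) cytoplasmic
  buffering capacity converting free-Ca²⁺ derivatives into total-Ca
  fluxes. Two constant balancing fluxes complete the decomposition: SR
  backflux \(B = k_{SERCA} \cdot c_{dia}\) (the rate required to balance
  SERCA at diastolic \[Ca²⁺\]) and sarcolemmal leak
  \(L = k_{NCX} \cdot c_{rest}\) (the rate required to balance NCX at
  resting \[Ca²⁺\]). These identities hold exactly in every report by
  construction.

Because the CaT recovery reflects SERCA *and* NCX, the default
`"ncx-subtracted"` mode subtracts the caffeine-derived NCX slope from the
CaT-recovery slope to isolate SERCA; `"lumped"` mode reports the raw
slope. Which convention a given laboratory uses varies, so both are
provided and the mode is recorded in every report.

## Calibration

The background-subtracted ratio \(R\) of the two emission channels maps
hyperbolically to free calcium,
\[
[\mathrm{Ca}^{2+}] = K_d \frac{R - R_{min}}{R_{max} - R},
\]
with the exact inverse used when synthesising fluorescence. FuraRed loses
resolving power at high \[Ca²⁺\]; ratios above 2.4 are flagged as
saturated. The saturation bound of 2.4 is the one published constant of
the default curve; \(R_{min} = 1.0\), \(R_{max} = 3.0\) and
\(K_d = 0.4\,\mu M\) are plausible stand-ins that **must** be overridden
with the constants of the user's own calibration. Saturated samples are
flagged (and capped at the value of the curve at the saturation ratio
only when \(R \ge R_{max}\), so no infinity can propagate); they are not
discarded, which keeps peak-time detection possible, but any transient
containing flagged samples marks its report `peak_unreliable`.

## The forward simulator

Every analysis stage is verified by parameter recovery against a forward
model with known ground truth. The simulated cell has a cytosol (free
\[Ca²⁺\] \(c\), µM) and an SR pool (total Ca \(s\), µM in cytosol-volume
equivalents):
\[
\beta \frac{dc}{dt} = J_{rel} + B + L - k_{SERCA} c - k_{NCX} c,
\qquad
\frac{ds}{dt} = k_{SERCA} c - B - J_{rel},
\]
with \(B = k_{SERCA} c_{rest}\) and \(L = k_{NCX} c_{rest}\) so that the
cell is self-consistently at rest, and \(J_{rel} = k_{caff}\, s\) after
caffeine onset (zero before). Each stimulus is an instantaneous event:
the fraction `fr` of the SR content moves to the cytosol (free \(c\)
jumps by \(fr \cdot s/\beta\), so the CaT amplitude is exactly
\(fr \cdot s/\beta\) and fractional release is cleanly recoverable).

**Trigger influx.** A per-beat model with only the terms above cannot
pace to a steady state: NCX extrudes a fraction
\(\approx fr \cdot k_{NCX}/(k_{SERCA}+k_{NCX})\) of the released Ca²⁺ on
every beat, and with no beat-wise Ca²⁺ entry the SR content decays
geometrically to zero. Real myocytes balance this loss with L-type
trigger Ca²⁺ entry. The simulator therefore deposits `stim_influx` µM of
trigger Ca²⁺ per stimulus, entering across the sarcolemma and assigned
to the SR pool (trigger Ca²⁺ that is rapidly resequestered). Routing the
entry through the SR rather than the cytosolic jump keeps the CaT
amplitude exactly \(fr \cdot s/\beta\). The default
`stim_influx = fr * sr_init * k_ncx / (k_serca + k_ncx)` makes
`sr_init` (approximately) the paced steady state, so simulations start
at, and stay at, their periodic regime.

**Caffeine emptying rate.** During caffeine, SERCA keeps cycling Ca²⁺
through the open SR, which slows the apparent recovery: the slow
eigenvalue of the caffeine phase is
\(\frac{k_{NCX}}{\beta}\cdot\frac{k_{caff}}{k_{caff}+(k_{SERCA}+k_{NCX})/\beta}\).
For the caffeine recovery to be a faithful NCX probe, SR emptying must be
fast against cytosolic removal; the default \(k_{caff} = 500\,s^{-1}\)
empties the SR within ~10 ms and keeps the eigenvalue bias on recovered
\(k_{NCX}\) at about 1% (at 50 s⁻¹ it would be ~9%).

**Protocol.** Defaults are 20 beats at 2 Hz with caffeine applied exactly
one pacing period after the last stimulus — in place of the next expected
beat, as with a rapid-switch caffeine puff at the end of a train. At that
moment the SR content equals its per-beat steady state, so the CaffT
amplitude is an unbiased SR-load probe and fractional release is
recovered to better than 1% noiselessly. A consequence is that the
pre-caffeine baseline ("resting" \[Ca²⁺\]) is the paced diastolic level,
not a long-quiescence level; the resting window is therefore the 50 ms
immediately before onset. With a long pre-caffeine gap instead, the SR
re-equilibrates a few percent below its paced steady state during the
gap, which biases fractional release upward by ~4–5% at the defaults —
both windows are configurable if that protocol is preferred.

Integration is fixed-step RK4 at `dt = 1 ms`, with stimulus events
applied between steps. Cumulative net sarcolemmal extrusion is
co-integrated, so the conservation identity
\(\beta c + s + \text{extruded} = \text{const}\) is monitored; the
residual is ~10⁻¹³ µM at the defaults and is asserted below
10⁻⁶ of the total-Ca scale in the tests.

**Rendering.** The simulated \(c(t)\) is downsampled to the camera rate
(100 Hz default, typical of sCMOS imaging of whole-cell transients),
converted to the noiseless ratio, and synthesised into two emission
channels (denominator held at a constant level, numerator = level ×
ratio, plus backgrounds). Gaussian noise is added per channel — not on
the ratio — so ratio noise is realistically heteroscedastic. "1% channel
noise" in the tests means `channel_sd = 1` against a denominator level
of 100.

What the generator deliberately does *not* emulate: dye bleaching and
compartmentalisation, motion artifacts, spatially resolved release
(sparks/waves), action-potential electrophysiology, nonlinear (Hill)
SERCA kinetics, or Ca²⁺-dependent buffering. Passing recovery tests
therefore demonstrates correctness of the analysis chain under the
model's assumptions, not robustness to every failure mode of real
recordings.

## Numerical choices in the analysis

* **Differentiation.** The recovery flux is obtained by Savitzky–Golay
  local-quadratic smoothing, estimating the smoothed value and its
  derivative with the same window (their noise contributions are
  uncorrelated at the window centre, which keeps the flux–Ca slope
  unbiased under noise). Defaults: 11 samples (110 ms at 100 Hz) for the
  CaT recovery and 41 samples for the ~10× slower caffeine recovery. The
  smoothing window is recorded in provenance. Half a window is trimmed
  at each end before fitting.
* **Fit window.** The slope is fitted over the decay between 90% and 10%
  of the amplitude above baseline, avoiding peak rounding and baseline
  noise. First-crossing with linear interpolation is used for all
  fraction-time metrics (ties broken by earliest time), and the fitted
  line has a free intercept — the backflux/leak constants imply a
  nonzero intercept, and the rate constant is defined as the slope only.
* **Caffeine peak.** The raw post-onset maximum of a noisy,
  hyperbolically calibrated trace near saturation carries a strong
  upward order-statistic bias. The default therefore back-extrapolates a
  mono-exponential fit of the caffeine recovery to the onset time
  (`peak_method = "fit"`); the raw maximum is available as
  `peak_method = "max"`. The fit is used only for the peak/SR-load
  estimate — the NCX rate constant always comes from the flux–Ca slope,
  which is the method this analysis exists to implement.
* **Windows.** Diastolic = mean over the last 50 ms before each
  stimulus; resting = mean over the 50 ms before caffeine onset. Beats
  whose segment would overlap the caffeine window are excluded, and the
  first 2 beats of the train are discarded before averaging
  (`discard_first_n`, covering the approach to the periodic regime).
* **Segmentation without metadata.** Peaks are local maxima of the
  lightly median-smoothed trace whose topographic prominence exceeds 4×
  a robust noise s.d. (MAD of the first difference / √2); on clean
  simulated trains this agrees with stimulus-anchored segmentation to
  within one sample.
* **Degenerate inputs.** All-masked ratios, flat traces, empty SRs,
  too-few fit points, zero Ca²⁺ variance and insufficient animal
  replication raise typed conditions (or warnings where the spec of the
  quantity allows a zero result); `full_report()` wraps stage failures
  with the stage name and emits a partial report.

## Precision and known limitations

With 1% channel noise at 100 Hz, the flux-slope estimate of
\(k_{SERCA}\) benefits from beat averaging (≈1–2% s.d.), but
\(k_{NCX}\) comes from a single caffeine transient: its absolute slope
error is roughly constant across the physiological range, so the
*relative* error grows as \(1/k_{NCX}\) (≈5–8% s.d. at
\(k_{NCX} = 40\,s^{-1}\)). A bias/variance scan over smoothing orders
and windows showed no setting materially better; this is an intrinsic
precision limit of derivative-based slope estimation on one transient,
worth keeping in mind when comparing low-NCX groups.

## Hierarchical statistics

Myocytes from one animal share an isolation and are not independent;
pooling cells across animals (pseudo-replication) inflates type-I error
roughly with the design effect \(1 + (m-1)\,\mathrm{ICC}\). Two
transparent animal-level procedures are provided, each labelled in its
output: a summarise-then-test route (per-animal means compared by Welch
t-test) and a two-level bootstrap (animals resampled with replacement,
then cells within animals; percentile CI; tail p-value). No mixed-model
likelihood machinery is used — the aim is a small, fully testable core
whose error calibration is itself verified by simulation:
`naive_vs_hierarchical_demo()` shows the naive pooled test's type-I
error rising monotonically with between-animal s.d. while the
animal-mean test stays at the nominal level. These Monte-Carlo checks
run on the cohort generator's ground-truth parameter tables directly
(the statistical question concerns nested variation, not the imaging
pipeline), with cohort sizes mirroring the motivating experiments:
7 animals per group, 30 cells per animal, 10% between-animal and 20%
between-cell fractional s.d., lognormal at both levels.

Multiple-testing control across the metric panel is deliberately out of
scope; p-values are reported raw.

## Problem sizes used in the shipped checks

Simulations use 20 beats at 2 Hz + caffeine (16.25 s at `dt` = 1 ms),
rendered at 100 Hz; the noisy-recovery grid is 3×3 rate-constant
combinations at one noisy cell each; the null-calibration runs use 2,000
(test) / 1,000 (acceptance script) simulated cohorts; the bootstrap
power check uses 30 cohorts × 400 bootstrap replicates. These sizes were
chosen so the whole verification suite runs in well under a minute on a
laptop while keeping Monte-Carlo bands tight enough to be meaningful.
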