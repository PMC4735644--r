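---
title: "Methods: quantifying beating behaviour in cardiomyocyte aggregates"
author: "autobeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying beating behaviour in cardiomyocyte aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autobeat)
```

## What this package measures

Stem-cell-derived cardiomyocytes cultured as three-dimensional aggregates
(embryoid bodies, EBs) beat spontaneously, and their intrinsic rate,
contractile strength, calcium handling and action-potential shape change
as the cells mature or are conditioned by chronic electrical pacing.
`autobeat` implements the four measurement channels such studies rest
on, plus relative qPCR quantification:

1. **Contractility from bright-field video**: threshold segmentation of
   the beating object, the fractional area change over time, beat
   detection as area minima, and the spontaneous beating frequency.
2. **Strain from particle image velocimetry (PIV)**: frame-pair
   displacement fields by multi-pass cross-correlation, a
   contraction-positive scalar strain rate, and the cumulative-strain /
   strain-per-beat metrics.
3. **Calcium transient kinetics** from fluorescence recordings:
   background-corrected normalized traces, time to peak (10 %-above-
   baseline rule), full width at half maximum (FWHM), and the decay
   time constant of an exponential fit.
4. **Action-potential (AP) features** from current-clamp voltage
   traces: maximum diastolic potential (MDP), peak, maximal upstroke
   velocity (dV/dt~max~), take-off potential, APD30/50/90, phase-4
   slope and spontaneous rate, with Tukey-fence classification of
   rapidly depolarizing cells.
5. **Delta-delta-Ct** fold changes normalized to a housekeeping gene
   (calsequestrin by default) and expressed relative to a control
   group.

Because no raw recordings accompany the study design this package
serves, every channel is validated against a synthetic-data generator
that emits videos, traces and tables with *known ground truth*:
contracting speckled disks with an analytic displacement field,
fluorescence transients with closed-form kinetics, AP trains whose
feature values are inputs rather than outputs, and Ct tables built from
prescribed fold changes.

## The synthetic generator as a measurement standard

The generator is first-class, tested code, not a fixture. Its defaults
encode the acquisition conditions of the study design it emulates:
stimulation and beating rates of 0.5, 1 and 2 Hz; bright-field video at
30 frames/s (15 used by one camera in the original setup); calcium
imaging at 100 frames/s; patch-clamp sampling at 10 kHz; upstroke
velocities of 24 mV/ms for ventricular-like cells and 88 mV/ms for
rapid depolarizers.

**Contraction videos.** A focus is a bright speckled disk (foreground
0.5–0.95, background 0.05 on a unit intensity scale) whose material
point at rest radius $r$ sits at $r\,(1 - a\,s(t))$, where $a$ is the
peak fractional linear contraction and $s(t) \in [0,1]$ a periodic
pulse waveform (raised cosine over a configurable duty fraction). The
speckle texture is generated once at rest and advected through this map
by bilinear interpolation, so the displacement field a frame-pair PIV
can observe equals the recorded truth; truth velocities are
frame-to-frame position differences, not instantaneous derivatives.
Segmented area, its minimum $(1-a)^2$, and the per-pair mean divergence
$2(\lambda_{t+1}/\lambda_t - 1)$ are all closed-form. Additive Gaussian
noise with `noise_sd = 0.05` against the 0.5 contrast corresponds to
SNR 10. One or two non-overlapping foci are supported; two foci with
different frequencies emulate independently beating areas in one field
of view.

**Calcium traces.** Each beat is a linear rise over `rise_time`
followed by $A e^{-t/\tau}$ decay, on a baseline with optional
background offset and photobleaching. The spec invariant
`rise_time + 3 tau < period` guarantees the transients resolve, so the
analytic truths are time to peak $0.9\,\mathrm{rise\_time}$ (from the
10 % crossing of a linear rise) and FWHM
$0.5\,\mathrm{rise\_time} + \tau \ln 2$. Recordings start in diastole
(`onset_delay`, default 0.1 s): a transient starting at the first
sample has no observable onset.

**AP trains.** Each cycle is piecewise: a linear phase-4 ramp from the
MDP at `phase4_slope`; a sigmoidal upstroke whose maximal slope equals
`dvdt_max` exactly (the logistic is truncated at ±6 scale units and
renormalized, and the scale compensates the truncation); and a
monotone cubic repolarization spline (`monoH.FC`) forced through the
30/50/90 % repolarization levels at exactly `apd30/apd50/apd90` after
the time of maximal upstroke velocity. The take-off potential follows
from the diastolic interval and the phase-4 slope; a short fixed-point
iteration reconciles the (weak) circular dependence between upstroke
width and diastolic duration. Morphology presets: `ventricular_like`
(MDP −60 mV, peak +30 mV, 24 mV/ms, APD90 400 ms, 1 Hz) and
`rapid_depolarizer` (MDP −50 mV, 88 mV/ms, APD90 160 ms, 2 Hz). The
repolarization spline is phenomenological; no ionic model is implied.

**What the generator does not emulate.** Real EB videos contain focus
drift, uneven illumination, debris and out-of-plane motion; real
calcium recordings contain motion artefacts (suppressed chemically in
the emulated protocol) and non-exponential late decay; real APs contain
baseline wander and electrode artefacts. Passing the recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every failure mode of real data.

## Contractility channel

Segmentation uses a deterministic default: an Otsu threshold computed
on the temporal **median frame**, applied fixed across frames (an
interactive "sliding scale" cannot be reproduced in tests), with an
optional additive offset and `quantile`/`fixed` alternatives. Because
the between-class variance of a cleanly bimodal histogram is maximal on
a *plateau* spanning the empty gap between modes, the threshold takes
the plateau midpoint; taking its first bin would park the threshold at
the edge of the background mode and let noise percolate into the
object. Per frame, the largest connected component is kept (ties broken
by centroid proximity to the previous frame); empty frames are flagged
and reported, never silently zeroed.

Beats are minima of the smoothed fractional-area trace — the object
shrinks on contraction, so "peaks of maximum contraction" are area
minima. The default moving average spans 3 frames; the contraction
depth of a candidate minimum is measured against the local maximum
within one refractory interval (default 0.25 s). The depth floor is
0.01, raised automatically to eight times the robust noise level of the
smoothed trace (median absolute successive difference / $\sqrt 2$):
with a fixed floor, segmentation jitter at SNR 10 masquerades as beats.
Frequency is reported two ways — event count over duration (robust to a
single missed beat; the default) and inverse median inter-beat interval
(robust to edge effects) — because which of the two an interactive
analysis used is not knowable; both agree on clean data.

## PIV and strain channel

Displacement between adjacent frames is estimated on interrogation
windows of 64, 32 and 16 px (overlap 0.5), each pass feeding the next
as integer window offsets (offset-only multi-pass; no window
deformation — adequate at the ≤ 7 px displacements of the fixtures and
a documented limitation for large strains). Windows are zero-meaned and
correlation-coefficient normalized; the correlation is computed by
zero-padded FFT and divided by the per-lag overlap area — without that
normalization the implicit triangular taper biases the subpixel fit
toward integer lags (classic peak locking); the acceptance suite holds
the RMS error at half-pixel shifts below 0.1 px. The integer peak is
refined by a 3-point Gaussian fit per axis (parabolic fallback when a
neighbour is non-positive). Vectors fail validation when the
primary-to-secondary peak ratio is below 1.3 or they exceed a global
median-absolute-deviation fence; failed vectors are flagged and
replaced by the local 3 × 3 median.

The scalar strain rate is the **negative divergence** of the velocity
field over the frame interval, so it is positive while tissue
converges; central differences on the interrogation grid are exact for
affine fields (the analytic inflow $u=-kx,\ v=-ky$ recovers $2k/\Delta t$
to machine precision). Which scalar an interactive PIV tool integrated
is not determinable, so the divergence was chosen and the sign
convention is exposed (`sign_convention = "divergence"`). The strain
trace averages the scalar over a mask; for quantitative comparison with
ground truth the mask must be eroded by half the final window size so
every vector is supported by object texture — windows straddling the
object edge mix moving and static pattern and bias the field low.
Cumulative strain is the time-integral of the positive part of the mean
strain rate (`sum(pmax(rate, 0)) * frame_interval`, dimensionless); the
time-integral reading was chosen over a raw sum so the value is
invariant under temporal resampling (verified within 10 % under 2×
upsampling), and strain per beat divides by the number of contractions.
Velocity heat maps convert to µm/s and clip to fixed colour limits
(default 0–28 µm/s) with the clipped fraction reported.

## Calcium channel

The corrected trace is ROI mean minus background-ROI mean per frame,
smoothed (default 5 samples at 100 frames/s, configurable off) and
min–max normalized over the recording. Transient windows are
**peak-anchored**: prominent peaks (above half the global amplitude,
separated by `min_interval`) are found first, and each window starts at
the last upward crossing of baseline + 10 % of amplitude before its
peak. The literal "windows delimited by 10 %-level crossings" reading
spawns spurious windows from noise wiggles around the level at SNR 10;
on clean data both constructions give identical windows. The 10 % level
is amplitude-relative (`baseline + 0.1 × (peak − baseline)`), not
`1.1 × baseline` — required for the timing identities to hold under
intensity offsets, and verified by affine-invariance tests. Per-beat
baseline is the median of the last 10 % of the previous window (global
minimum for the first beat).

Time to peak runs from the interpolated 10 % upward crossing to the
peak sample; FWHM between the interpolated half-amplitude crossings of
the two flanks. The decay fit is nonlinear least squares of
$F(t) = b + A e^{-t/\tau}$ from the peak to the start of the next beat,
with $t$ zeroed at the peak and **the asymptote $b$ free**, initialized
at the window baseline: holding $b$ fixed at a tail estimate biases
$\tau$ by up to −9 % whenever the previous transient has not fully
decayed (the invariant allows a residue up to $e^{-3} \approx 5\,\%$).
Start values are $A_0 = \mathrm{peak} - b$ and $\tau_0$ = time to fall
to $1/e$ of the amplitude; non-convergence and non-positive $\tau$ are
flagged, never silently dropped.

**Precision of the tau fit.** The Fisher information of the
three-parameter exponential model bounds the relative standard
deviation of $\hat\tau$ at 100 frames/s and amplitude-to-noise 10 to
about 6.5/5.5/4.6 % for $\tau$ = 0.2/0.3/0.5 s even with a ~5 s decay
window — an ideal estimator lands within 10 % of truth in only
~88/93/97 % of runs per $\tau$. The packaged fit operates within ~10 %
of these bounds. The tau simulation study therefore uses isolated
transients with a long diastolic tail (0.2 Hz, 5 s recordings, one
transient each, 67 seeds per $\tau$, 201 fits per noise level), pooling
the $\tau$ grid: measured bias −0.03 % at amplitude-SNR 20 and 92 % of
fits within 10 % at SNR 10. The within-10 % fraction sits at the
information-theoretic boundary and fluctuates a few points either side
of 90 % across seed sets; that is a property of the estimation problem,
not of the implementation.

## AP channel

Event detection thresholds the smoothed derivative (Savitzky–Golay,
0.5 ms half-width) at 10 mV/ms with a 0.2 s refractory period; the
default threshold sits ~6 noise standard deviations above the
derivative noise floor at 0.5 mV voltage noise, where a 5 mV/ms
threshold produced spurious events. Peaks are voltage maxima within
half a cycle after each upstroke; MDPs are minima between consecutive
upstrokes.

Estimating dV/dt~max~ is the delicate step: the rapid-depolarizer
upstroke has a time-scale of ~0.24 ms, so any fixed smoothing window
wide enough to control noise attenuates its derivative peak (a 0.5 ms
moving average costs ~8 %), while the raw maximum of a noisy derivative
is biased upward. The packaged estimator exploits that the log of a
sigmoidal upstroke's derivative is locally parabolic: a quadratic is
fitted to the log of the **raw** central differences over the top
region of the smoothed derivative, the vertex giving the peak value and
subsample time. The fitted curvature yields the upstroke time-scale
$\hat k$, from which the only systematic error of raw central
differences — chord-slope attenuation $\tanh(x)/x$ at
$x = \Delta t/2\hat k$ — is divided back out. The vertex is capped at
the best raw sample times $1 + 1/(4\hat k^2)$, which keeps a
flat-topped derivative (a constant-slope upstroke, where the parabola
model does not apply) from being inflated by its corners. The final
value is the median over three fit-region widths (top 35/45/55 % of
the peak), because a derivative-noise spike can hijack the region
selected at one threshold but not consistently at all three. Validated
on both morphologies at 0–0.5 mV noise: per-cell error (median over 4
beats) stays below 4 %; a 50 mV/ms sawtooth recovers 50.2.

Other features: MDP is the minimum of a 2 ms-averaged trace near the
detected diastolic minimum (the region is flat, so the wide window
suppresses the min-of-noise bias without distorting the value); APDx
runs from the time of dV/dt~max~ (the `peak` reference is available) to
the repolarization crossing of `peak − x% × (peak − MDP)`, located on
the smoothed trace and refined by a local linear regression of the raw
voltage over ±1.5 ms (a single-sample interpolation inherits the full
noise; the regression averages it). The take-off potential is the
voltage at the last sample before dV/dt exceeds 10 % of dV/dt~max~,
found by walking **backward** from the derivative peak (a forward
search latches onto derivative noise ahead of the upstroke foot); an
absolute-threshold variant is exposed. The phase-4 slope is the
least-squares slope over the middle 50 % of the MDP-to-take-off
interval.

Rapid depolarizers are cells whose dV/dt~max~ exceeds Q3 + 1.5 × IQR of
the cohort; quartiles use linear interpolation between order statistics
(type 7 — the flagged set can differ between quantile conventions on
tiny cohorts, so the convention is fixed and documented), and the
comparison is strict so an all-equal cohort flags nothing. The fence is
applied to the pooled cohort by default — a cell's label should not
depend on how the cohort is split into groups — with a per-group
option.

## qPCR channel

Technical replicates are averaged to a mean Ct per sample and gene.
Per sample, $\Delta Ct = Ct_{target} - Ct_{reference}$; per gene,
$\Delta\Delta Ct$ subtracts the control group's mean $\Delta Ct$; the
fold change is $2^{-\Delta\Delta Ct}$ (amplification efficiency fixed
at 2; efficiency correction is out of scope). Group summaries are the
arithmetic mean ± s.e.m. of per-sample folds, so the control group's
geometric mean fold is exactly 1 and its arithmetic mean ≈ 1. Per-
sample global Ct offsets (pipetting) cancel in $\Delta Ct$ by
construction, which the generator exercises explicitly.

## Study sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which the recovery statistics are
stable: 60 videos (3 frequencies × 20 seeds, 10 s at 30 frames/s) for
frequency recovery; 5 speckle shifts for the PIV oracle; 201 fits per
noise level for the tau study; 100 cells × 4 beats for the AP study;
1000 random cohorts for the classifier oracle. The whole test suite
runs in under a minute; `scripts/acceptance.R` in about half a minute.

## Interfaces

The package's functions are the interface: analyses compose as
`frame_stack` → `segment_stack` → `area_trace` → `detect_beats` →
`beat_frequency`, and similarly per channel, with plain data.frames in
and out. Videos read and write as multipage 16-bit TIFF
(`read_frame_stack`/`write_frame_stack`); traces as two-column CSV
(`read_trace_csv`/`write_trace_csv`). A worked end-to-end example lives
in the README; `scripts/acceptance.R` re-runs every channel against
fresh synthetic data and writes the headline numbers as JSON.

## Known limitations

- Offset-only multi-pass PIV: no window deformation, so accuracy
  degrades for strains large within a single window.
- The segmentation default assumes a single dominant object per ROI and
  roughly stable illumination; it tracks drift only through the
  largest-component rule.
- Calcium analysis is single-ROI; no spark/wave spatial analysis, no
  ratiometric calibration to absolute concentration.
- The AP morphology model is phenomenological; take-off potential
  depends on the (configurable) 10 % rule and differs from the
  generator's ramp endpoint by construction (~2 mV), which is a
  definitional, not numerical, difference.
- Tukey-fence classification on cohorts of 4–6 cells is sensitive to
  the quantile convention; type 7 is fixed here.
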