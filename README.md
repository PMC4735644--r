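# autobeat

Quantitative analysis of the autonomous beating behaviour of
stem-cell-derived cardiomyocyte aggregates (embryoid bodies): beating
frequency from bright-field video, contractile strain from particle
image velocimetry, calcium transient kinetics, action-potential
features with rapid-depolarizer classification, and ΔΔCt qPCR fold
changes. It is written for labs that condition nascent cardiomyocytes
(e.g. by chronic electrical pacing) and need the downstream
measurements to be reproducible, scripted and testable rather than
interactive.

## The measurements

**Contractility.** Frames are threshold-segmented (Otsu on the temporal
median frame by default), the object area per frame is normalized to
its maximum — the *fractional area change* — and beats are detected as
minima of that trace (the object shrinks on contraction). The
spontaneous frequency is reported both as beats/duration and as the
inverse median inter-beat interval.

**Strain.** Displacement fields between adjacent frames are estimated
by multi-pass FFT cross-correlation (64/32/16 px windows, 3-point
Gaussian subpixel refinement, peak-ratio + median-fence vector
validation). The scalar strain rate is the contraction-positive
negative divergence, −(∂u/∂x + ∂v/∂y)/Δt; its spatial mean over the
beating area traces contraction over time, and

- cumulative strain = Σ max(rate, 0) · Δt,
- strain per beat = cumulative strain / number of contractions.

**Calcium.** Traces are ROI mean − background mean, min–max
normalized. Per beat: time to peak from the 10 %-above-baseline
crossing, FWHM between half-amplitude crossings, and τ from a
nonlinear fit of baseline + A·e^(−t/τ) from the peak to the next beat.

**Action potentials.** Spontaneous APs are detected on the smoothed
dV/dt; per AP: peak, MDP, amplitude, dV/dt_max (scale-free
log-derivative peak fit), take-off potential, APD30/50/90 from the time
of dV/dt_max, phase-4 slope and rate. Cells whose dV/dt_max exceeds
Q3 + 1.5 × IQR of the cohort (type-7 quartiles, strict inequality) are
classified as rapid depolarizers.

**qPCR.** ΔΔCt fold changes 2^(−ΔΔCt), normalized to calsequestrin
(CASQ2) by default and expressed relative to the control group.

Every channel ships with a synthetic-data generator producing videos,
traces and Ct tables with known ground truth (analytic displacement
fields, closed-form transient kinetics, prescribed AP features), which
is what the test suite and the acceptance script measure recovery
against.

## Worked example

```r
library(autobeat)

# A 10-second recording of a field with two independently beating foci,
# one paced-like at 2 Hz and one at the native ~1 Hz rate (SNR ~10).
spec <- synthetic_video_spec(
  beats = list(beat_waveform_spec(frequency = 1, amplitude = 0.12),
               beat_waveform_spec(frequency = 2, amplitude = 0.12)),
  duration = 10, frame_rate = 30, image_size = c(64, 128),
  noise_sd = 0.05, seed = 42)
video <- gen_contraction_video(spec)

left <- matrix(FALSE, 64, 128); left[, 1:64] <- TRUE
rois <- analyze_rois(video$stack, list(left, !left))
```

```
ROI 1: 10 beats, 1.00 Hz (count), 1.00 Hz (interval), min fractional area 0.789
ROI 2: 20 beats, 2.00 Hz (count), 2.00 Hz (interval), min fractional area 0.789
```

The two regions beat independently at 1 and 2 Hz; each contracts to
~79 % of its maximal area (amplitude 0.12 → (1−0.12)² ≈ 0.774, plus
pixelation). Calcium kinetics per beat:

```r
ca <- gen_calcium_trace(synthetic_calcium_spec(
  beat_frequency = 1, tau_decay = 0.3, rise_time = 0.05,
  noise_sd = 2, duration = 5, seed = 42))
trace <- as_corrected_trace(ca$trace$time_s, ca$trace$value)
transient_metrics(trace)
```

```
  beat time_to_peak_s fwhm_s  tau_s       A r_squared
1    1           0.04 0.2220 0.3048 98.8556    0.9939
2    2           0.04 0.2196 0.3056 99.6901    0.9943
3    3           0.04 0.2184 0.3025 99.9642    0.9945
```

The fitted τ ≈ 0.30 s matches the generator's 0.3 s; the FWHM ≈ 0.22 s
is the analytic 0.5·rise + τ·ln 2 = 0.233 s within ~1.5 frames. AP
features for the two morphologies and the outlier rule:

```r
for (m in c("ventricular_like", "rapid_depolarizer")) {
  g   <- gen_ap_trace(synthetic_ap_spec(m, noise_sd = 0.3, n_beats = 4, seed = 1))
  tr  <- voltage_trace(g$trace$time_s, g$trace$voltage_mV)
  met <- analyze_ap_trace(tr)$metrics
  # median over beats characterises the cell
}
```

```
ventricular_like  MDP  -60.0 mV  dV/dt_max  23.5 mV/ms  APD90 400.2 ms  rate 1.00 Hz
rapid_depolarizer MDP  -50.1 mV  dV/dt_max  87.5 mV/ms  APD90 160.2 ms  rate 2.00 Hz
```

```r
coh <- gen_cohort(20, normal_mean = 24, normal_sd = 3,
                  outlier_values = 88, seed = 1)
classify_rapid_depolarizers(coh$cohort$dvdt_max)
```

```
Tukey fence: Q3 26.5, IQR 3.4, cutoff 31.5 -> 1/21 flagged (5%)
```

The one planted 88 mV/ms cell — and only it — exceeds the fence.

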