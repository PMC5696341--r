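# endoflow

Quantification of endothelial cell responses to fluid shear stress from
live-cell imaging and velocimetry data.

Endothelial cells lining blood vessels sense the frictional force of flowing
blood (wall shear stress) and respond with calcium signaling, elongation and
alignment along the flow axis, junction remodeling, and polarized transport
of membrane proteins toward the downstream cell pole. `endoflow` implements
the complete measurement chain used to quantify these responses in
flow-chamber experiments, for experimentalists who have fluorescence movies,
stained monolayer images, or phase-contrast velocimetry grids and need
reproducible numbers out of them. A fully seeded synthetic-data generator
produces every input with recorded ground truth, so the whole chain is
validated against known answers.

## What it computes

**Calcium traces.** Movies of a single-wavelength calcium indicator (OGB-1)
are segmented by temporal averaging and Otsu thresholding; per-cell traces
are extracted and the slow photobleaching trend is removed by a
Levenberg–Marquardt fit of a second-degree polynomial plus exponential decay
under the asymmetric loss

L(y, ŷ) = (y − ŷ)² (sign(y − ŷ) + α)⁴,  α > 0,

with `y` the model prediction: for α ≈ 0.8 a trend that overshoots the data
costs ((1+α)/(1−α))⁴ ≈ 6.5·10³ times more than the same undershoot, so the
fitted trend tracks the baseline underneath transient calcium peaks instead
of averaging through them. Corrected fluorescence is converted to
concentration with per-cell calibration levels (ionomycin-saturated Fmax,
EDTA-chelated Fmin) and the indicator dissociation constant:

Ca(t) = K_d · (F(t) − F_min) / (F_max − F(t)),  K_d = 170 nM.

Spikes are maximal runs of samples more than two noise standard deviations
above the baseline lasting at least three seconds; per-spike duration,
amplitude and area under the curve feed per-cell summaries and group
comparisons (Mann–Whitney U with exact small-sample enumeration, Welch's
t-test).

**Morphometry.** Per-cell elongation factor (length along the flow direction
divided by width), orientation angle in [0°, 90°] from second central
moments, percent junction coverage / gap area by Otsu thresholding of a
junction marker, organelle (Golgi) polarity by centroid projection,
protein-polarization profiles along the normalized cell body with a
downstream-fraction index, and exponential repolarization kinetics
d(t) = d∞ − (d∞ − d0)·exp(−t/τ).

**Wall shear stress.** Velocity-field post-processing (no-flow baseline
subtraction, averaging with a 180°-rotated acquisition to cancel directional
bias) and conversion of speed maps to shear with the parallel-plate laminar
formula τ_w = 6µQ/(bh²), reported in dyn cm⁻².

## Worked example

Synthesize one cell's trace with three known spikes, then run the full
per-cell chain (bleach correction → calibration → spike detection):

```r
library(endoflow)
truth <- traceGroundTruth(baselineCa = 125,
                          spikeOnsets    = c(120, 310, 470),
                          spikeDurations = c(9, 6, 12),
                          spikeAmplitudes = c(6, 4.5, 8), seed = 7)
trace <- synthTrace(truth)
res <- processTrace(trace)
res$summary
#>  n_spikes mean_duration_s mean_amplitude_nM baseline_nM noise_sd_nM
#>         3               9          7.300412    125.1072   0.6224462
res$spikes[, c("start_s", "duration_s", "amplitude_nM", "auc_baseline_nM_s")]
#>  start_s duration_s amplitude_nM auc_baseline_nM_s
#>      120          9     7.179151          49.17440
#>      310          6     5.690240          22.34070
#>      470         12     9.031847          85.01937
```

All three spikes are found at their true onsets with exact durations; the
resting calcium (125 nM) is recovered to 0.1 nM. Amplitudes read slightly
high (e.g. 7.2 vs a painted 6 nM) because the amplitude of a spike is the
*maximum* of its noisy samples over the baseline — an extreme-order
statistic — plus a small inflation of early spikes when multiplicative
bleaching is corrected by subtraction; the methods vignette quantifies both
effects.

Shear mapping from a synthetic parallel-plate field:

```r
sv <- synthVelocityField(Q = 0.15, b = 0.5, h = 0.04)  # cm^3/s, cm, cm
sv$tauTruth
#> [1] 8.775          # dyn cm^-2, = 6*mu*Q/(b*h^2) at mu = 0.0078
max(abs(shearValues(shearMap(sv$field))[sv$field@mask] - sv$tauTruth))
#> [1] 0              # pipeline equals the analytic truth exactly
```

Group studies run through `synthCondition()` (presets `"scramble"` and
`"kd"` mirror reported control/knockdown spike statistics from flow-chamber recordings) and
`runCalciumPipeline()`, which returns per-cell tables and Mann–Whitney /
Welch comparisons; `renderReport()` writes CSV + JSON bundles.

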