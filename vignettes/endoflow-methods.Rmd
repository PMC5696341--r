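---
title: "Methods: quantifying endothelial responses to flow"
author: "endoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying endothelial responses to flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoflow)
```

# Scope and model

`endoflow` measures three families of endothelial flow responses:

1. **Calcium signaling** — flow-triggered transient rises of intracellular
   calcium, read out with a single-wavelength indicator at 1 frame s⁻¹.
2. **Morphometry** — elongation/alignment of cells with the flow axis,
   junction integrity, organelle polarity and the kinetics of protein
   repolarization after flow reversal.
3. **Wall shear stress** — the mechanical stimulus itself, from gridded
   velocity measurements over a parallel-plate chamber.

Each stage is written against explicit contracts with degenerate-input
behavior spelled out, and every stage can be exercised on synthetic data
with recorded ground truth.

# Calcium pipeline

## Acquisition model

A recording has three phases back to back: `flow` (default 600 s), then
`ionomycin` (180 s; the ionophore saturates the indicator, giving the
per-cell maximum fluorescence Fmax) and `edta` (180 s; chelation gives the
per-cell minimum Fmin), all sampled at `dt = 1` s. Only the flow phase is
kinetic data; the terminal phases are level estimates, summarized as the
median of their last 30 samples (`estimateFmax`, `estimateFmin`). The median
is robust to the transition transient after solution exchange; if a phase
has not plateaued, the value is by definition the median of its final
samples, which is documented rather than guarded against.

## Segmentation

Cells are found on the temporal mean of all frames, thresholded with Otsu's
method (256 bins over the min–max range, candidate thresholds at interior
bin edges, ties broken toward the lowest threshold — this reproduces the
classic formulation exactly on 8-bit data). Connected components are
4-connected and labeled 1..K in raster order, which makes label identity
deterministic across platforms. Touching cells are *not* split: no watershed
is applied, so confluent monolayers are under-segmented at contact points.
This is a known limitation; traces of merged cells average their members.

## Photobleach correction

The flow-phase trend is modeled as `c0 + c1·t + c2·t² + amp·exp(t/τ)` with
the linear coefficient and the characteristic time constrained negative
(the exponential must decay). Because spikes are wide and frequent enough to
occupy a sizable fraction of a trace, an ordinary least-squares trend would
be pulled upward; the fit instead minimizes the asymmetric loss

$$L(y,\hat y) = (y-\hat y)^2\,(\mathrm{sign}(y-\hat y)+\alpha)^4$$

with $y$ the model prediction and $\hat y$ the measurement. For residual
$r = y - \hat y$ the penalty ratio between equal-magnitude over- and
under-estimation is $((1+\alpha)/(1-\alpha))^4$ for $\alpha \in (0,1)$ —
about $6.5\times 10^3$ at the default $\alpha = 0.8$ — so the trend rides
the baseline *below* the spikes. Two properties worth knowing:

* The ratio is maximal as $\alpha \to 1$ and *declines* again for
  $\alpha > 1$ (the ratio becomes $((1+\alpha)/(\alpha-1))^4$). The
  monotone "lower-envelope" effect of increasing $\alpha$ therefore holds on
  $(0, 1]$ only; the default grid for per-trace selection spans 0.2–2.0 but
  typical data select values near 0.8.
* On spike-free noise the optimum sits a fixed number of noise SDs *below*
  the baseline median. This offset is constant in time, and the detrending
  convention (below) cancels it.

Optimization is Levenberg–Marquardt (`minpack.lm`), with the loss expressed
through the residual transform $r\,(\mathrm{sign}(r)+\alpha)^2$ so that the
sum of squares equals the asymmetric objective, plus an L2 penalty
`l2Lambda · c2²` (scale-normalized; default weight 1e-6) that discourages
runaway curvature. The objective is non-convex in τ, so unless the caller
supplies a start the fitter tries three characteristic times (span/12,
span/3, span) and keeps the best; a fit whose residuals are at numerical
zero is reported converged regardless of step-tolerance diagnostics.
Initialization follows the scale of the data: `c0 = median(F)`,
`c1 = c2 = 0⁻`, `amp = F(0) − median(F)`.

**Per-trace α selection** (`selectAlpha`) scores each grid value by
|median(F − trend)| over the sub-median samples — the spike-free baseline —
and returns the minimizer, falling back to 0.8 on ties. The criterion is
deterministic and reproduces the typical ≈ 0.8 behavior on realistic traces.

**Detrending** subtracts the trend and re-anchors at its last flow value:
`F_corr(t) = F(t) − trend(t) + trend(t_lastflow)`. Re-anchoring keeps the
corrected flow phase commensurable with the subsequently recorded
calibration phases (which are never detrended), so per-cell Fmin/Fmax apply
directly. It also cancels the constant below-baseline offset of the
asymmetric fit. Subtraction corrects an *additive* bleach exactly; if the
true bleach is multiplicative, spikes recorded early (when the trend is
high) are inflated relative to the end-of-flow anchor by up to
`B(0)/B(end) − 1` — about 6% at the generator's default bleach — and this
is visible as a small positive amplitude bias in recovery benchmarks.

## Calibration

$$\mathrm{Ca}(t) = K_d\,\frac{F(t)-F_{\min}}{F_{\max}-F(t)},\qquad
K_d = 170\ \mathrm{nM\ (OGB\text{-}1)}.$$

A sample exactly midway between the levels maps to $K_d$; the transform is
strictly increasing on $(F_{\min}, F_{\max})$ and invariant to rescaling all
intensities. Samples within `1e-6·(Fmax−Fmin)` of Fmax, or at/below Fmin,
cannot be calibrated; they are clamped into `[0, 10·Kd]` and flagged
`clipped` so downstream statistics stay finite and auditable.

## Spike detection and statistics

The baseline is the trace median. The noise SD is a median absolute
deviation about the baseline computed over the samples at or below the 75th
percentile, which makes it insensitive to the spikes about to be detected.
The consistency constant matters: the classic 1.4826 is calibrated for a
full normal sample, and under this truncation it underestimates a Gaussian
SD by ≈ 27%, silently lowering the "2 SD" threshold to ≈ 1.46 SD and
raising the false-positive rate on a 600-sample spikeless trace from under
1% to ≈ 20%. The estimator therefore uses `1/qnorm(0.6875) ≈ 2.046`, the
exact constant for the lower-75% truncation (the median of |x − median|
over that subset of a standard normal is `qnorm(0.6875)`). Contamination by
actual spikes shifts the 75th percentile slightly upward and inflates the
estimate by ~10–25% at 10% spike occupancy — a conservative direction.

A spike is a maximal run of consecutive samples strictly above
`baseline + 2·noiseSd` lasting at least 3 s (a run of `n` samples at step
`dt` lasts `n·dt`). Runs are never merged across sub-threshold gaps, and a
run touching the end of the trace counts only if already long enough —
the simplest reading of the duration rule, stated so users can change it.
Per spike:

* `duration_s` — time above threshold;
* `amplitude_nM` — max concentration in the window minus baseline;
* `auc_nM_s` — trapezoidal area over the window of the trace minus its
  **global minimum**;
* `auc_baseline_nM_s` — the same area referenced to the baseline.

Both AUC variants are reported deliberately. On a noiseless trace they are
identical (the minimum of a spikes-up trace *is* the baseline), but on a
noisy trace the global minimum is an extreme order statistic
(≈ 3.2 noise SDs below baseline at 600 samples), so the global-minimum
variant carries a noise-floor offset of roughly `3σ·duration` that grows
with recording length. Recovery benchmarks and cross-condition effect sizes
should therefore use `auc_baseline_nM_s`; `auc_nM_s` is retained as the
primary literal definition.

Group comparison uses the Mann–Whitney U test with midranks; the two-sided
p-value is exact (full enumeration of all C(n, nA) assignments) when both
groups have ≤ 8 observations and no ties, else a normal approximation with
tie and continuity corrections (verified against `wilcox.test` in the test
suite). Welch's t-test is available alongside. Per-cell spike means are
undefined (NA) for non-responders, so comparisons run over responding cells.

# Synthetic data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes with recorded ground truth.

**Traces.** Calcium is baseline plus boxcar spikes whose first and last
in-window samples sit at half amplitude; this "smoothed-edge boxcar" makes
the number of samples above any low threshold equal `duration/dt` exactly,
so duration ground truth is exact by construction. Fluorescence is the
inverse calibration transform of the calcium series, multiplied by the
normalized bleach trend (`bleachMode = "additive"` offsets instead, to test
the correction under both truths), followed by exponential approaches to
Fmax and Fmin in the terminal phases (time constant 20 s) and additive
Gaussian noise. All randomness flows from explicit integer seeds; equal
seeds give bit-identical traces.

Defaults, chosen once as the package's study conditions:

* Calibration scale `fmin = 50`, `fmax = 250` a.u. (dynamic range 5, typical
  of intracellular single-wavelength indicators), `Kd = 170` nM.
* `noiseSd = 0.2` a.u. ≈ 0.5 nM at a 120–125 nM baseline. Rationale: a
  2-SD threshold rule that reliably picks up ~4 nM mean-amplitude spikes
  implies sub-nanomolar effective noise on per-cell traces (which average
  hundreds of pixels).
* Bleach: `1 − 2·10⁻⁵ t + 0.05·e^{t/−250}` — ≈ 6% loss over 10 min,
  consistent with low-light acquisition.
* Phase plan 600/180/180 s at `dt = 1` s.

**Condition presets.** `conditionPreset("scramble")` (n = 347 cells, 87%
responders, amplitude 4.1 nM, duration 8.6 s, baseline 125 nM) and
`conditionPreset("kd")` (n = 339, 94%, 7.8 nM, 10.7 s, 121 nM) mirror the
reported control/knockdown group statistics. Amplitudes are drawn from
normals truncated at 0 with SD = SEM·√n (SEMs 0.3 and 0.6 nM). Durations
are truncated normals (≥ 3 s, the definitional minimum) with the reported
means and a 30% CV: scaling the reported duration uncertainties by √n would
give SDs of 13 and 75 s, whose truncated means (15.7 and 53 s) contradict
the very means being emulated and produce spikes covering most of the flow
phase — outside the validity domain of a median baseline. Spike counts per
responding cell are shifted-Poisson with means 2.5 and 3.5; onsets are
uniform over the flow phase with non-overlap guards.

**What the generator does not emulate.** Real traces have non-boxcar spike
shapes (fast rise, slower decay), correlated noise, cell-to-cell
calibration variability, motion, and focus drift. Passing recovery tests on
generator output demonstrates the *measurement chain* is correct under the
stated model; it does not certify performance on pathological real data.

**Monolayers, profiles, fields.** `synthMonolayer` places non-overlapping
ellipses on a jittered grid with controlled elongation/orientation, and
renders a junction image as the cell-border skeleton with a chosen fraction
of border pixels knocked out — the full skeleton is returned as the
coverage denominator. `synthPolarSeries` draws downstream fractions
relaxing as `d(t) = d∞ − (d∞ − d0)·e^{−t/τ}` (defaults τ = 30 min,
d0 = 0.25, d∞ = 0.75, matching flow-reversal repolarization over ~2 h).
`synthVelocityField` builds a uniform interior speed `Q/(b·h)` with an
invalid one-voxel rim and packages the analytic shear truth computed by the
same expression the pipeline uses, so equality is exact, not approximate.

# Morphometry conventions

* **Flow axis** is `+x` of the image frame by default (downstream =
  increasing x); it is a parameter everywhere and recorded in reports.
* **Elongation** uses projected extents — length along the flow axis divided
  by perpendicular width, both as max-minus-min pixel extents — not the
  major/minor axis ratio. A cell lying across the flow has EF < 1, which is
  the behavior wanted when tracking alignment. Width is the maximum
  perpendicular extent.
* **Orientation** comes from second central moments, folded into [0°, 90°]
  as the absolute acute angle to the flow axis.
* Cells touching the image border are excluded (clipped shapes), with a
  message giving the count; profile extraction likewise rejects
  border-clipped cells.
* **Profiles**: intensity is summed across the perpendicular direction at
  each station along the flow axis; each side's distance to the nucleus
  center is normalized so the cell ends map to exactly ±1. Background is
  the 5th percentile of the raw profile (robust, parameter-logged),
  subtracted and floored at zero. Note a perfectly uniform profile is
  zeroed by its own background estimate — real profiles always vary.
  The polarization index is the downstream trapezoidal area over the total;
  mirroring a profile maps the index to its complement exactly.
* **Golgi polarity**: signed centroid projection with a 1 µm deadband
  (closed interval → `unpolarized`), giving the three observed classes.
* **Nuclear-signal response**: percentage of cells above a threshold per
  ROI (user-supplied or Otsu-derived from pooled intensities), with a
  logarithmic fit `pct = a·ln(τ_w) + c` across ROIs and a plateau level
  reported when the two highest-shear points differ by < 2 points.

# Wall shear mapping

All shear arithmetic is CGS (dyn, cm, s); SI speeds are converted on load.
Corrections preserve the order used at acquisition: subtract the no-flow
baseline image (gradient imperfections), then average with the acquisition
physically rotated 180° about the x axis — re-registered by reversing row
order and negating the y (and z) component — which cancels any directional
bias that enters both acquisitions with the same sign. Both corrections are
linear, so their order commutes.

The parallel-plate formula `τ_w = 6µQ/(bh²)` is applied per voxel with
`Q = s̄·b·h`, i.e. the measured in-plane speed is treated as the
cross-sectional (depth-averaged) mean, giving `τ = 6µs̄/h`; the voxel width
cancels algebraically. If the measurement reflects the mid-plane *peak* of
the parabolic profile instead, `profile = "parabolic"` divides by 1.5.
Default viscosity `µ = 0.0078` dyn·s·cm⁻² (culture medium at 37 °C),
overridable.

# Numerical choices and degenerate inputs

* Otsu on a constant image, empty ROIs, empty groups, all-zero profiles,
  zero noise SD, missing calibration phases: all raise informative errors
  rather than returning NaN.
* Calibration clamps un-calibratable samples into `[0, 10·Kd]` with a flag.
* Exact Mann–Whitney enumeration is capped at 8 per group (≤ 12 870
  arrangements), keeping it deterministic and fast.
* The repolarization fit requires ≥ 4 timepoints and rejects constant
  series ("no relaxation").
* Non-converged bleach fits are returned with `converged = FALSE` and a
  warning, never silently.

# Validation scales

The shipped test suite validates, among ~400 assertions: exact equivalence
of the spike detector with a run-enumeration oracle (all 5-level traces up
to length 5 exhaustively, plus hundreds of seeded random traces up to
length 20); bleach-trend recovery to < 1% RMSE on noiseless trends and
asymmetric-vs-symmetric baseline bias on 100 seeded spiked traces;
calibration round trips to < 1e-9 nM; full-pipeline parameter recovery on
two synthetic conditions of 300 cells each (matched-spike comparison within
3 standard errors, responder fractions within 3 binomial SEs); exact
agreement of shear maps with the analytic parallel-plate truth; and
morphometry recovery (orientation within 2°, elongation within 5%,
repolarization τ within 10% at 5% noise over 100 seeded repeats). These
problem sizes mirror the reference assay design (two conditions of ~340 cells) while
keeping the whole suite around a minute of compute.

# Known limitations

* Confluent monolayers are under-segmented (no watershed); the calcium
  pipeline is typically run on well-separated indicator-loaded cells.
* Additive detrending of multiplicative bleach inflates early-spike
  amplitudes by up to the bleach depth (~6% at defaults); amplitude means
  additionally read high by an extreme-order-statistic bias
  (≈ E[max of k noise samples]) inherent to the max-over-window amplitude
  definition.
* The global-minimum AUC definition embeds a noise-floor rectangle; use the
  baseline-referenced variant for effect sizes.
* Fmin/Fmax are estimated from raw terminal phases; bleaching accrued
  during flow scales both levels and cancels in the calibration ratio only
  to first order.
* The repolarization fit assumes a single-exponential relaxation; the
  two-sided profile machinery does not model nuclear exclusion or
  organelle-specific geometry.
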