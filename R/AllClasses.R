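#' @import methods
NULL

.PHASES <- c("flow", "ionomycin", "edta", "none")

#' Per-cell fluorescence trace
#'
#' A single cell's raw (arbitrary-unit) fluorescence as a function of time,
#' with one acquisition-phase label per sample. The acquisition protocol has
#' three phases recorded back to back: `flow` (indicator imaging under flow),
#' `ionomycin` (ionophore saturation, used for the per-cell Fmax) and `edta`
#' (calcium chelation, used for the per-cell Fmin).
#'
#' @slot cellId integer cell identifier.
#' @slot t numeric, sample times in seconds; strictly increasing, constant step.
#' @slot f numeric, fluorescence in arbitrary units.
#' @slot phase character, one of `"flow"`, `"ionomycin"`, `"edta"`, `"none"`.
#' @export
setClass("CellTrace",
  slots = c(cellId = "integer", t = "numeric", f = "numeric",
            phase = "character"))

setValidity("CellTrace", function(object) {
  n <- length(object@t)
  if (length(object@f) != n || length(object@phase) != n)
    return("t, f and phase must have equal lengths")
  if (!all(object@phase %in% .PHASES))
    return(sprintf("phase labels must be in {%s}", paste(.PHASES, collapse = ", ")))
  if (n >= 2) {
    dt <- diff(object@t)
    if (any(dt <= 0)) return("t must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(dt)) return("t must have a constant step")
  }
  TRUE
})

#' Multi-frame fluorescence movie
#'
#' @slot frames 3-D numeric array, rows x cols x time, arbitrary units.
#' @slot dt numeric(1), frame interval in seconds.
#' @slot phase character, one acquisition-phase label per frame.
#' @export
setClass("FluorescenceMovie",
  slots = c(frames = "array", dt = "numeric", phase = "character"))

setValidity("FluorescenceMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be a 3-D array (rows x cols x time)")
  if (length(object@phase) != d[3]) return("one phase label per frame required")
  if (!all(object@phase %in% .PHASES)) return("invalid phase labels")
  if (length(object@dt) != 1 || object@dt <= 0) return("dt must be a single positive number")
  TRUE
})

#' Labeled cell image
#'
#' Integer label image: 0 is background, cells are labeled 1..K in raster
#' order of their first pixel; each label's region is 4-connected.
#'
#' @slot labels integer matrix.
#' @slot pixelSize numeric(1), microns per pixel (NA if unknown).
#' @export
setClass("CellLabelMap",
  slots = c(labels = "matrix", pixelSize = "numeric"))

setValidity("CellLabelMap", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric/integer")
  if (any(l < 0)) return("labels must be non-negative")
  k <- max(l)
  if (k > 0 && !all(seq_len(k) %in% l))
    return("labels must be consecutive positive integers")
  TRUE
})

#' Photobleaching trend model
#'
#' Slow-decay model for a fluorescence trace: a second-degree polynomial plus
#' an exponential, `c0 + c1*t + c2*t^2 + amp*exp(t/tau)`, fitted with an
#' asymmetric loss so that transient calcium peaks (which sit above the trend)
#' are penalized far less than samples below the trend. The linear coefficient
#' and the exponential characteristic time are both constrained negative, so
#' the exponential term decays.
#'
#' @slot c0,c1,c2 polynomial coefficients (a.u., a.u./s, a.u./s^2); `c1 <= 0`.
#' @slot amp exponential amplitude (a.u.).
#' @slot tau exponential characteristic time in seconds, constrained `< 0`.
#' @slot alpha asymmetry meta-parameter of the loss, `> 0`.
#' @slot l2Lambda weight of the L2 penalty on `c2`.
#' @slot converged logical(1).
#' @slot lossValue final value of the objective.
#' @export
setClass("BleachModel",
  slots = c(c0 = "numeric", c1 = "numeric", c2 = "numeric",
            amp = "numeric", tau = "numeric", alpha = "numeric",
            l2Lambda = "numeric", converged = "logical",
            lossValue = "numeric"))

setValidity("BleachModel", function(object) {
  if (object@c1 > 1e-12) return("c1 must be <= 0")
  if (object@tau >= 0) return("tau must be < 0 (decay)")
  if (object@alpha <= 0) return("alpha must be > 0")
  TRUE
})

#' Calibration constants for a single-wavelength calcium indicator
#'
#' @slot kd indicator dissociation constant in nM (default 170, OGB-1).
#' @slot fmin,fmax per-cell fluorescence at zero and saturating calcium (a.u.).
#' @slot fminN,fmaxN number of samples each level estimate used.
#' @export
setClass("CalibrationConstants",
  slots = c(kd = "numeric", fmin = "numeric", fmax = "numeric",
            fminN = "integer", fmaxN = "integer"))

setValidity("CalibrationConstants", function(object) {
  if (object@kd <= 0) return("kd must be > 0")
  if (!(object@fmax > object@fmin)) return("fmax must exceed fmin")
  TRUE
})

#' Calibrated calcium concentration trace
#'
#' @slot cellId integer cell identifier.
#' @slot t seconds.
#' @slot ca calcium concentration in nM.
#' @slot clipped logical per sample: TRUE where the fluorescence sat outside
#'   the calibratable range and the value was clamped.
#' @export
setClass("CalciumTrace",
  slots = c(cellId = "integer", t = "numeric", ca = "numeric",
            clipped = "logical"))

setValidity("CalciumTrace", function(object) {
  n <- length(object@t)
  if (length(object@ca) != n || length(object@clipped) != n)
    return("t, ca and clipped must have equal lengths")
  if (any(object@ca[!object@clipped] < -1e-9))
    return("ca must be >= 0 where not clipped")
  TRUE
})

#' Ground truth for one synthetic calcium trace
#'
#' Everything the generator needs to synthesize a fluorescence trace and that
#' a benchmark needs to score the pipeline against: resting calcium, spike
#' times/durations/amplitudes, the photobleach trend coefficients, the noise
#' level and the calibration constants.
#'
#' @slot baselineCa resting calcium, nM.
#' @slot spikeOnsets,spikeDurations,spikeAmplitudes per-spike truth (s, s, nM).
#' @slot bleachCoeffs named numeric: c0, c1, c2, amp, tau (tau < 0).
#' @slot noiseSd additive Gaussian noise on fluorescence, a.u.
#' @slot fmin,fmax,kd calibration truth (a.u., a.u., nM).
#' @slot seed integer RNG seed.
#' @export
setClass("TraceGroundTruth",
  slots = c(baselineCa = "numeric", spikeOnsets = "numeric",
            spikeDurations = "numeric", spikeAmplitudes = "numeric",
            bleachCoeffs = "numeric", noiseSd = "numeric",
            fmin = "numeric", fmax = "numeric", kd = "numeric",
            seed = "integer"))

setValidity("TraceGroundTruth", function(object) {
  ns <- length(object@spikeOnsets)
  if (length(object@spikeDurations) != ns || length(object@spikeAmplitudes) != ns)
    return("spike onset/duration/amplitude vectors must have equal lengths")
  if (ns > 0 && any(object@spikeDurations <= 0)) return("spike durations must be > 0")
  if (!(object@fmax > object@fmin && object@fmin > 0)) return("need fmax > fmin > 0")
  if (object@kd <= 0) return("kd must be > 0")
  co <- object@bleachCoeffs
  need <- c("c0", "c1", "c2", "amp", "tau")
  if (!all(need %in% names(co))) return("bleachCoeffs must be named c0,c1,c2,amp,tau")
  if (co[["tau"]] >= 0) return("bleach tau must be < 0 (decay)")
  TRUE
})

#' Parameters of a synthetic experimental condition
#'
#' Population-level parameters used to draw per-cell spike ground truth.
#' Amplitudes are drawn from a normal truncated at 0; durations from a normal
#' truncated at the 3 s detectability minimum (shorter events are, by
#' definition, not spikes).
#'
#' @slot name condition label.
#' @slot nCells number of cells.
#' @slot responderProb probability a cell spikes at least once.
#' @slot spikesPerResponderMean Poisson mean of the (>=1-conditioned) spike count.
#' @slot durationMean,durationSd spike duration distribution, s.
#' @slot amplitudeMean,amplitudeSd spike amplitude distribution, nM.
#' @slot baselineMean resting calcium, nM.
#' @export
setClass("ConditionConfig",
  slots = c(name = "character", nCells = "integer", responderProb = "numeric",
            spikesPerResponderMean = "numeric",
            durationMean = "numeric", durationSd = "numeric",
            amplitudeMean = "numeric", amplitudeSd = "numeric",
            baselineMean = "numeric"))

setValidity("ConditionConfig", function(object) {
  if (object@nCells < 1) return("nCells must be >= 1")
  if (object@responderProb < 0 || object@responderProb > 1)
    return("responderProb must be in [0, 1]")
  if (any(c(object@durationMean, object@amplitudeMean, object@baselineMean,
            object@spikesPerResponderMean) <= 0))
    return("means must be > 0")
  TRUE
})

#' Protein intensity profile along the flow axis
#'
#' Background-subtracted intensity as a function of normalized position along
#' the cell body: 0 is the nucleus center, +1 the downstream cell end, -1 the
#' upstream end (each side rescaled independently).
#'
#' @slot cellId integer.
#' @slot position numeric in [-1, 1], endpoints exactly +/-1.
#' @slot intensity non-negative a.u.
#' @slot timeMin acquisition time in minutes (NA if not part of a series).
#' @export
setClass("PolarizationProfile",
  slots = c(cellId = "integer", position = "numeric", intensity = "numeric",
            timeMin = "numeric"))

setValidity("PolarizationProfile", function(object) {
  if (length(object@position) != length(object@intensity))
    return("position and intensity must have equal lengths")
  if (length(object@position) >= 2) {
    if (abs(min(object@position) + 1) > 1e-9 || abs(max(object@position) - 1) > 1e-9)
      return("position endpoints must be exactly -1 and +1")
  }
  if (any(object@intensity < 0)) return("intensity must be >= 0")
  TRUE
})

#' Gridded velocity field
#'
#' 2-D grids of velocity components measured over a flow chamber, with the
#' chamber geometry needed for the parallel-plate shear formula.
#'
#' @slot vx,vy,vz component grids; `vz` may be a 0x0 matrix when absent.
#' @slot mask logical matrix of valid voxels.
#' @slot b voxel width, cm.
#' @slot h chamber height, cm.
#' @slot units `"m/s"` or `"cm/s"`.
#' @export
setClass("VelocityField",
  slots = c(vx = "matrix", vy = "matrix", vz = "matrix", mask = "matrix",
            b = "numeric", h = "numeric", units = "character"))

setValidity("VelocityField", function(object) {
  if (!identical(dim(object@vx), dim(object@vy)))
    return("vx and vy grids must be congruent")
  if (length(object@vz) > 0 && !identical(dim(object@vz), dim(object@vx)))
    return("vz grid must be congruent with vx")
  if (!identical(dim(object@mask), dim(object@vx)))
    return("mask must be congruent with the grids")
  if (object@b <= 0 || object@h <= 0) return("b and h must be > 0")
  if (!object@units %in% c("m/s", "cm/s")) return("units must be m/s or cm/s")
  TRUE
})

#' Wall shear stress map
#'
#' @slot tau shear stress grid, dyn cm^-2.
#' @slot mu dynamic viscosity used, dyn s cm^-2.
#' @slot mask logical matrix of valid voxels.
#' @export
setClass("ShearMap",
  slots = c(tau = "matrix", mu = "numeric", mask = "matrix"))

setValidity("ShearMap", function(object) {
  if (!identical(dim(object@mask), dim(object@tau)))
    return("mask must be congruent with tau")
  if (any(object@tau[object@mask] < 0)) return("tau must be >= 0 on valid voxels")
  TRUE
})

#' Calcium pipeline analysis report
#'
#' @slot cells per-cell summary table.
#' @slot spikes per-spike table.
#' @slot comparisons list of group-comparison results.
#' @slot config the configuration the run used, serialized verbatim.
#' @export
setClass("CalciumReport",
  slots = c(cells = "data.frame", spikes = "data.frame",
            comparisons = "list", config = "list"))
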