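#' Construct calibration constants
#'
#' @param fmin,fmax per-cell fluorescence at zero / saturating calcium, a.u.
#' @param kd indicator dissociation constant, nM (170 for OGB-1).
#' @param fminN,fmaxN sample counts behind each level estimate.
#' @return a [CalibrationConstants-class].
#' @export
calibrationConstants <- function(fmin, fmax, kd = 170, fminN = NA_integer_,
                                 fmaxN = NA_integer_) {
  if (fmax <= fmin) stop("fmax must exceed fmin")
  new("CalibrationConstants", kd = kd, fmin = fmin, fmax = fmax,
      fminN = as.integer(fminN), fmaxN = as.integer(fmaxN))
}

# median of the last k samples of a phase
.phaseLevel <- function(trace, phase, k = 30) {
  idx <- .phaseIdx(trace, phase, minSamples = k)
  f <- traceValues(trace)[idx]
  list(level = stats::median(utils::tail(f, k)), n = min(k, length(f)))
}

#' Estimate the saturating-calcium fluorescence level (Fmax)
#'
#' Median of the last `k` samples of the ionophore phase, by which point the
#' indicator has equilibrated at saturation. The median is robust to the
#' transition transient; if the phase has not plateaued the value is simply
#' the median of its final samples (documented behavior).
#'
#' @param trace a [CellTrace-class] with an `ionomycin` phase.
#' @param k number of terminal samples (default 30).
#' @return the level, a.u.
#' @export
estimateFmax <- function(trace, k = 30) .phaseLevel(trace, "ionomycin", k)$level

#' Estimate the zero-calcium fluorescence level (Fmin)
#'
#' Median of the last `k` samples of the chelator (EDTA) phase.
#'
#' @inheritParams estimateFmax
#' @return the level, a.u.
#' @export
estimateFmin <- function(trace, k = 30) .phaseLevel(trace, "edta", k)$level

#' Estimate both calibration levels from a trace
#'
#' @inheritParams estimateFmax
#' @param kd indicator dissociation constant, nM.
#' @return a [CalibrationConstants-class].
#' @export
estimateConstants <- function(trace, kd = 170, k = 30) {
  mx <- .phaseLevel(trace, "ionomycin", k)
  mn <- .phaseLevel(trace, "edta", k)
  calibrationConstants(fmin = mn$level, fmax = mx$level, kd = kd,
                       fminN = mn$n, fmaxN = mx$n)
}

#' Convert fluorescence to calcium concentration
#'
#' Applies the single-wavelength indicator formula samplewise to the
#' flow-phase fluorescence:
#' `Ca(t) = Kd * (F(t) - Fmin) / (Fmax - F(t))`.
#' Samples with `F >= fmax - eps` or `F <= fmin` cannot be calibrated; they
#' are clamped into `[0, 10*kd]` and flagged `clipped`, keeping downstream
#' statistics finite and auditable.
#'
#' @param trace a [CellTrace-class] (bleach-corrected); only flow-phase
#'   samples are converted.
#' @param constants a [CalibrationConstants-class].
#' @return a [CalciumTrace-class] over the flow phase.
#' @export
calibrateTrace <- function(trace, constants) {
  if (constants@fmax <= constants@fmin) stop("fmax must exceed fmin")
  idx <- .phaseIdx(trace, "flow")
  t <- traceTime(trace)[idx]
  f <- traceValues(trace)[idx]
  eps <- 1e-6 * (constants@fmax - constants@fmin)
  hi <- f >= constants@fmax - eps
  lo <- f <= constants@fmin
  ca <- constants@kd * (f - constants@fmin) / (constants@fmax - f)
  ca[hi] <- 10 * constants@kd
  ca[lo] <- 0
  calciumTrace(cellId(trace), t, ca, clipped = hi | lo)
}
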