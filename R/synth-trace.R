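#' Default acquisition phase plan
#'
#' Mirrors the acquisition protocol: 10 min of imaging under flow at one frame
#' per second, then 3 min after ionophore addition (per-cell Fmax) and 3 min
#' after chelator addition (per-cell Fmin).
#'
#' @return named numeric vector of phase durations in seconds.
#' @export
defaultPhasePlan <- function() c(flow = 600, ionomycin = 180, edta = 180)

#' Default photobleaching trend coefficients
#'
#' A mild decay (about 6% signal loss over 10 min), consistent with
#' low-light acquisition. Trend: `c0 + c1*t + c2*t^2 + amp*exp(t/tau)`.
#'
#' @return named numeric vector c0, c1, c2, amp, tau.
#' @export
defaultBleachCoeffs <- function() {
  c(c0 = 1, c1 = -2e-5, c2 = 0, amp = 0.05, tau = -250)
}

#' Construct trace ground truth
#'
#' @param baselineCa resting calcium, nM.
#' @param spikeOnsets,spikeDurations,spikeAmplitudes per-spike truth (s, s, nM).
#' @param bleachCoeffs named numeric c0, c1, c2, amp, tau; tau < 0. Use
#'   `c(c0=1, c1=0, c2=0, amp=0, tau=-1)` for a flat (bleach-free) trend.
#' @param noiseSd additive Gaussian noise on fluorescence, a.u.
#' @param fmin,fmax,kd calibration truth.
#' @param seed integer RNG seed for the noise draw.
#' @return a [TraceGroundTruth-class] object.
#' @export
traceGroundTruth <- function(baselineCa = 125, spikeOnsets = numeric(0),
                             spikeDurations = numeric(0),
                             spikeAmplitudes = numeric(0),
                             bleachCoeffs = defaultBleachCoeffs(),
                             noiseSd = 0.2, fmin = 50, fmax = 250, kd = 170,
                             seed = 1L) {
  new("TraceGroundTruth", baselineCa = baselineCa,
      spikeOnsets = as.numeric(spikeOnsets),
      spikeDurations = as.numeric(spikeDurations),
      spikeAmplitudes = as.numeric(spikeAmplitudes),
      bleachCoeffs = bleachCoeffs, noiseSd = noiseSd,
      fmin = fmin, fmax = fmax, kd = kd, seed = as.integer(seed))
}

# evaluate the bleach trend
.bleachTrend <- function(coeffs, t) {
  coeffs[["c0"]] + coeffs[["c1"]] * t + coeffs[["c2"]] * t^2 +
    coeffs[["amp"]] * exp(t / coeffs[["tau"]])
}

# noiseless calcium series over a time grid (flow-phase model):
# baseline plus boxcar spikes whose first and last in-window samples sit at
# half amplitude (the "smoothed edges"), so that the number of samples above
# any low threshold equals duration/dt exactly.
.caSeries <- function(truth, t) {
  ca <- rep(truth@baselineCa, length(t))
  ns <- length(truth@spikeOnsets)
  if (ns == 0) return(ca)
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  for (k in seq_len(ns)) {
    o <- truth@spikeOnsets[k]
    d <- truth@spikeDurations[k]
    A <- truth@spikeAmplitudes[k]
    idx <- which(t >= o - dt / 2 & t < o + d - dt / 2)
    n <- length(idx)
    if (n == 0) next
    shape <- rep(A, n)
    shape[1] <- A / 2
    shape[n] <- A / 2
    ca[idx] <- ca[idx] + shape
  }
  ca
}

#' Ground-truth calcium series for a synthetic trace
#'
#' The noiseless calcium concentration over the flow phase, exactly as the
#' generator painted it (boxcar spikes with half-amplitude edge samples).
#'
#' @param truth a [TraceGroundTruth-class].
#' @param phasePlan named durations, see [defaultPhasePlan()].
#' @param dt sampling interval, s.
#' @return numeric vector of nM values, one per flow-phase sample.
#' @export
truthCalcium <- function(truth, phasePlan = defaultPhasePlan(), dt = 1) {
  tFlow <- seq(0, phasePlan[["flow"]] - dt, by = dt)
  .caSeries(truth, tFlow)
}

#' Fluorescence of a single-wavelength indicator at a given calcium level
#'
#' Inverse of the calibration curve:
#' `F = (fmin*kd + fmax*ca) / (kd + ca)`.
#'
#' @param ca calcium, nM.
#' @param fmin,fmax,kd indicator constants.
#' @return fluorescence, a.u.
#' @export
fluorescenceForCa <- function(ca, fmin, fmax, kd) {
  (fmin * kd + fmax * ca) / (kd + ca)
}

#' Synthesize one fluorescence trace
#'
#' Builds the noiseless calcium series, maps it through the indicator curve,
#' applies the photobleach trend (multiplicatively by default), appends the
#' ionophore (F to fmax) and chelator (F to fmin) calibration phases as
#' exponential approaches, and adds Gaussian noise. The trend is frozen at its
#' last flow-phase value during the calibration phases (illumination-driven
#' bleaching accrued during flow scales those phases but the short terminal
#' phases themselves are treated as trend-free level measurements).
#'
#' @param truth a [TraceGroundTruth-class].
#' @param phasePlan named durations with flow, ionomycin, edta in that order.
#' @param dt sampling interval, s.
#' @param bleachMode `"multiplicative"` (trend scales the signal) or
#'   `"additive"` (trend offsets the signal).
#' @param settleTau time constant of the approach to fmax/fmin during the
#'   calibration phases, s.
#' @return a [CellTrace-class]; deterministic given `truth@seed`.
#' @export
synthTrace <- function(truth, phasePlan = defaultPhasePlan(), dt = 1,
                       bleachMode = c("multiplicative", "additive"),
                       settleTau = 20) {
  bleachMode <- match.arg(bleachMode)
  stopifnot(dt > 0)
  need <- c("flow", "ionomycin", "edta")
  if (!identical(names(phasePlan)[seq_along(need)], need))
    stop("phasePlan must contain flow, ionomycin, edta in that order")

  flowDur <- phasePlan[["flow"]]
  ns <- length(truth@spikeOnsets)
  if (ns > 0) {
    bad <- which(truth@spikeOnsets < 0 |
                 truth@spikeOnsets + truth@spikeDurations > flowDur)
    if (length(bad))
      stop(sprintf("spike %d lies outside the flow phase", bad[1]))
  }

  tFlow <- seq(0, flowDur - dt, by = dt)
  ca <- .caSeries(truth, tFlow)
  fClean <- fluorescenceForCa(ca, truth@fmin, truth@fmax, truth@kd)
  # the indicator curve approaches fmax asymptotically; a spike whose
  # fluorescence enters the calibration guard band is unrecoverable
  if (any(fClean >= truth@fmax - 1e-6 * (truth@fmax - truth@fmin))) {
    peak <- which.max(fClean)
    off <- which(truth@spikeOnsets <= tFlow[peak] &
                 truth@spikeOnsets + truth@spikeDurations > tFlow[peak])
    stop(sprintf("saturation: spike %s drives fluorescence to >= fmax",
                 if (length(off)) off[1] else "?"))
  }

  trend <- .bleachTrend(truth@bleachCoeffs, tFlow)
  bn <- trend / trend[1]
  fFlow <- if (bleachMode == "multiplicative") fClean * bn else
    fClean + (trend - trend[1])
  scaleEnd <- bn[length(bn)]
  offEnd <- trend[length(trend)] - trend[1]

  tIono <- seq(flowDur, flowDur + phasePlan[["ionomycin"]] - dt, by = dt)
  tEdta <- seq(max(tIono) + dt, max(tIono) + phasePlan[["edta"]], by = dt)

  fmaxEff <- if (bleachMode == "multiplicative") truth@fmax * scaleEnd else
    truth@fmax + offEnd
  fminEff <- if (bleachMode == "multiplicative") truth@fmin * scaleEnd else
    truth@fmin + offEnd
  fEndFlow <- fFlow[length(fFlow)]
  fIono <- fmaxEff + (fEndFlow - fmaxEff) * exp(-(tIono - flowDur) / settleTau)
  fEndIono <- fIono[length(fIono)]
  fEdta <- fminEff + (fEndIono - fminEff) * exp(-(tEdta - tEdta[1] + dt) / settleTau)

  f <- c(fFlow, fIono, fEdta)
  t <- c(tFlow, tIono, tEdta)
  phase <- c(rep("flow", length(tFlow)), rep("ionomycin", length(tIono)),
             rep("edta", length(tEdta)))
  if (truth@noiseSd > 0)
    f <- f + .withSeed(truth@seed, stats::rnorm(length(f), 0, truth@noiseSd))
  cellTrace(1L, t, f, phase)
}
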