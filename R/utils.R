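# internal helpers

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Construct a per-cell fluorescence trace
#'
#' @param cellId integer cell id.
#' @param t sample times, s.
#' @param f fluorescence, a.u.
#' @param phase per-sample phase labels (`"flow"`, `"ionomycin"`, `"edta"`,
#'   `"none"`); a single value is recycled.
#' @return a [CellTrace-class] object.
#' @export
cellTrace <- function(cellId, t, f, phase = "flow") {
  if (length(phase) == 1) phase <- rep(phase, length(t))
  new("CellTrace", cellId = as.integer(cellId), t = as.numeric(t),
      f = as.numeric(f), phase = as.character(phase))
}

#' Construct a calibrated calcium trace
#'
#' @param cellId integer cell id.
#' @param t sample times, s.
#' @param ca calcium concentration, nM.
#' @param clipped logical per sample (default all FALSE).
#' @return a [CalciumTrace-class] object.
#' @export
calciumTrace <- function(cellId, t, ca, clipped = rep(FALSE, length(t))) {
  new("CalciumTrace", cellId = as.integer(cellId), t = as.numeric(t),
      ca = as.numeric(ca), clipped = as.logical(clipped))
}

# sampling interval of a trace
.dt <- function(trace) {
  t <- traceTime(trace)
  if (length(t) < 2) stop("trace has fewer than 2 samples")
  t[2] - t[1]
}

# index set of a phase; error when absent
.phaseIdx <- function(trace, phase, minSamples = 1) {
  idx <- which(tracePhase(trace) == phase)
  if (length(idx) < minSamples)
    stop(sprintf("phase '%s' missing or shorter than %d samples", phase, minSamples))
  idx
}
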