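#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("tracePhase", function(object) standardGeneric("tracePhase"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("shearValues", function(object) standardGeneric("shearValues"))

#' @rdname accessors
#' @export
setMethod("cellId", "CellTrace", function(object) object@cellId)

#' @rdname accessors
#' @export
setMethod("cellId", "CalciumTrace", function(object) object@cellId)

#' @rdname accessors
#' @export
setMethod("traceTime", "CellTrace", function(object) object@t)

#' @rdname accessors
#' @export
setMethod("traceTime", "CalciumTrace", function(object) object@t)

#' @rdname accessors
#' @export
setMethod("traceValues", "CellTrace", function(object) object@f)

#' @rdname accessors
#' @export
setMethod("traceValues", "CalciumTrace", function(object) object@ca)

#' @rdname accessors
#' @export
setMethod("tracePhase", "CellTrace", function(object) object@phase)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "CellLabelMap", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("nCells", "CellLabelMap", function(object) as.integer(max(object@labels)))

#' @rdname accessors
#' @export
setMethod("shearValues", "ShearMap", function(object) object@tau)

setMethod("show", "CellTrace", function(object) {
  cat(sprintf("CellTrace (cell %d): %d samples, dt = %g s; phases: %s\n",
              object@cellId, length(object@t),
              if (length(object@t) > 1) diff(object@t[1:2]) else NA,
              paste(unique(object@phase), collapse = "/")))
})

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf("CalciumTrace (cell %d): %d samples, median %.1f nM, %d clipped\n",
              object@cellId, length(object@t),
              stats::median(object@ca), sum(object@clipped)))
})

setMethod("show", "FluorescenceMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FluorescenceMovie: %d x %d px, %d frames, dt = %g s\n",
              d[1], d[2], d[3], object@dt))
})

setMethod("show", "CellLabelMap", function(object) {
  cat(sprintf("CellLabelMap: %d x %d px, %d cells\n",
              nrow(object@labels), ncol(object@labels), max(object@labels)))
})

setMethod("show", "BleachModel", function(object) {
  cat(sprintf(paste0("BleachModel: c0=%.4g c1=%.4g c2=%.4g amp=%.4g tau=%.4g",
                     " (alpha=%.2g, converged=%s)\n"),
              object@c0, object@c1, object@c2, object@amp, object@tau,
              object@alpha, object@converged))
})

setMethod("show", "CalibrationConstants", function(object) {
  cat(sprintf("CalibrationConstants: Kd=%g nM, Fmin=%.4g (n=%d), Fmax=%.4g (n=%d)\n",
              object@kd, object@fmin, object@fminN, object@fmax, object@fmaxN))
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf("VelocityField: %d x %d grid (%s), b=%g cm, h=%g cm\n",
              nrow(object@vx), ncol(object@vx), object@units, object@b, object@h))
})

setMethod("show", "ShearMap", function(object) {
  v <- object@tau[object@mask]
  cat(sprintf("ShearMap: %d x %d grid, mu=%g dyn s cm^-2, range %.3g-%.3g dyn cm^-2\n",
              nrow(object@tau), ncol(object@tau), object@mu,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ConditionConfig", function(object) {
  cat(sprintf(paste0("ConditionConfig '%s': %d cells, responderProb=%.2f, ",
                     "duration %g+/-%g s, amplitude %g+/-%g nM, baseline %g nM\n"),
              object@name, object@nCells, object@responderProb,
              object@durationMean, object@durationSd,
              object@amplitudeMean, object@amplitudeSd, object@baselineMean))
})

setMethod("show", "CalciumReport", function(object) {
  cat(sprintf("CalciumReport: %d cells, %d spikes, %d comparisons\n",
              nrow(object@cells), nrow(object@spikes), length(object@comparisons)))
})
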